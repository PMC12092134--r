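// Planar articulated forward-dynamics engine.
//
// Rigid-body tree with a floating planar base (x, z, orientation) and
// revolute joints; equations of motion assembled by recursive
// Newton-Euler (bias forces + unit-acceleration mass-matrix columns) and
// solved by dense Cholesky.  Muscles are ideal cables (via points plus
// planar wrap circles) in series with Hill-type contractile/elastic
// machinery; ground contacts are unilateral spring-dampers with smoothed
// Coulomb friction; soft joint limits and midshaft bone-stress sections
// complete the force model.  Fixed-step semi-implicit Euler by default,
// classical RK4 as an alternative.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct V2 {
  double x, z;
};
inline V2 v2(double x, double z) { V2 v; v.x = x; v.z = z; return v; }
inline V2 operator+(V2 a, V2 b) { return v2(a.x + b.x, a.z + b.z); }
inline V2 operator-(V2 a, V2 b) { return v2(a.x - b.x, a.z - b.z); }
inline V2 operator*(double s, V2 a) { return v2(s * a.x, s * a.z); }
inline double dot(V2 a, V2 b) { return a.x * b.x + a.z * b.z; }
inline double cross(V2 a, V2 b) { return a.x * b.z - a.z * b.x; }
inline double norm(V2 a) { return std::sqrt(a.x * a.x + a.z * a.z); }
// omega z-hat x r in the plane
inline V2 omcross(double om, V2 r) { return v2(-om * r.z, om * r.x); }

struct Wrap {
  int after;   // wrap sits between anchors `after` and `after+1` (0-based)
  int body;
  double cx, cz, r;
  int dir;     // +1 cable runs CCW around the circle, -1 CW
};

struct Muscle {
  std::vector<int> body;
  std::vector<double> px, pz;
  std::vector<Wrap> wraps;
  double fmax, lopt, tl, vmax_abs, fva, flw, sestr, pekrel, peeng;
  bool rigid;
};

struct Contact {
  int body;
  double px, pz, k, c, mu;
};

struct Bone {
  int body;
  double frac, A, I, c, fail;
  std::vector<int> subtree;  // descendant bodies, excluding `body` itself
};

struct PointForce {
  int body;
  double lx, lz;     // local application point
  V2 P, F;           // world point and force
};

inline double fl_curve(double l, double lopt, double w) {
  double u = (l - lopt) / (w * lopt);
  double f = 1.0 - u * u;
  return f > 0 ? f : 0.0;
}

// force-velocity; v in fibre lengths per second, shortening positive
inline double fv_curve(double v_rel, double a) {
  if (v_rel <= 0) return 1.0;            // eccentric plateau
  if (v_rel >= 1) return 0.0;
  return (1.0 - v_rel) * a / (a + v_rel);
}

inline double pe_force(double l, double lopt, double fmax, double krel,
                       double engage) {
  double strain = (l - lopt) / lopt - engage;
  return strain > 0 ? krel * fmax * strain : 0.0;
}

class Engine {
public:
  int nb, nj, n, na, nc, nbo;
  bool fixed_base;
  double grav, total_mass;
  std::vector<int> parent;                    // -1 for root
  std::vector<double> ancx, ancz, offset;     // joint attachment (per body)
  std::vector<double> mass, moi, comx, comz, seglen;
  std::vector<double> jlo, jhi, jk, jc;       // soft limits (per joint = body-1)
  std::vector<Contact> contacts;
  std::vector<Muscle> muscles;
  std::vector<Bone> bones;

  // workspace
  std::vector<double> ang, ca, sa;
  std::vector<V2> pos, vel, acc, acom, comw, velcom;
  std::vector<double> om, al;
  std::vector<V2> Facc; std::vector<double> Macc;
  std::vector<double> Mmat, Cvec, Q, qdd_ws;
  std::vector<std::vector<int> > chain;       // q-indices of joints root->body
  std::vector<PointForce> pf;                 // external point forces this eval
  // per-muscle outputs of the last deriv evaluation
  std::vector<double> mus_F, mus_vce, mus_lmtu, mus_Fce, mus_Fse, mus_Fpe,
      mus_vmtu, mus_act;
  std::vector<double> bone_stress_ws;
  double grf_x, grf_z;

  Engine(List spec) {
    nb = as<int>(spec["nb"]);
    nj = nb - 1;
    n = 3 + nj;
    grav = as<double>(spec["gravity"]);
    fixed_base = spec.containsElementNamed("fixed_base") ?
        as<bool>(spec["fixed_base"]) : false;
    parent = as<std::vector<int> >(spec["parent"]);
    ancx = as<std::vector<double> >(spec["anchor_x"]);
    ancz = as<std::vector<double> >(spec["anchor_z"]);
    offset = as<std::vector<double> >(spec["offset"]);
    mass = as<std::vector<double> >(spec["mass"]);
    moi = as<std::vector<double> >(spec["moi"]);
    comx = as<std::vector<double> >(spec["com_x"]);
    comz = as<std::vector<double> >(spec["com_z"]);
    seglen = as<std::vector<double> >(spec["seg_length"]);
    jlo = as<std::vector<double> >(spec["joint_lo"]);
    jhi = as<std::vector<double> >(spec["joint_hi"]);
    jk = as<std::vector<double> >(spec["limit_k"]);
    jc = as<std::vector<double> >(spec["limit_c"]);
    total_mass = 0;
    for (int i = 0; i < nb; i++) total_mass += mass[i];

    List cl = spec["contacts"];
    nc = cl.size();
    for (int i = 0; i < nc; i++) {
      List c = cl[i];
      Contact ct;
      ct.body = as<int>(c["body"]);
      ct.px = as<double>(c["px"]); ct.pz = as<double>(c["pz"]);
      ct.k = as<double>(c["k"]); ct.c = as<double>(c["c"]);
      ct.mu = as<double>(c["mu"]);
      contacts.push_back(ct);
    }

    List ml = spec["muscles"];
    na = ml.size();
    for (int i = 0; i < na; i++) {
      List m = ml[i];
      Muscle mu;
      mu.body = as<std::vector<int> >(m["body"]);
      mu.px = as<std::vector<double> >(m["px"]);
      mu.pz = as<std::vector<double> >(m["pz"]);
      List wl = m["wraps"];
      for (int w = 0; w < wl.size(); w++) {
        List ws = wl[w];
        Wrap wr;
        wr.after = as<int>(ws["after"]);
        wr.body = as<int>(ws["body"]);
        wr.cx = as<double>(ws["cx"]); wr.cz = as<double>(ws["cz"]);
        wr.r = as<double>(ws["r"]); wr.dir = as<int>(ws["dir"]);
        mu.wraps.push_back(wr);
      }
      mu.fmax = as<double>(m["fmax"]);
      mu.lopt = as<double>(m["lopt"]);
      mu.tl = as<double>(m["tl"]);
      mu.vmax_abs = as<double>(m["vmax_abs"]);
      mu.fva = as<double>(m["fv_shape"]);
      mu.flw = as<double>(m["fl_width"]);
      mu.sestr = as<double>(m["se_strain"]);
      mu.pekrel = as<double>(m["pe_k_rel"]);
      mu.peeng = as<double>(m["pe_engage"]);
      mu.rigid = mu.tl < 1e-7;
      muscles.push_back(mu);
    }

    List bl = spec["bones"];
    nbo = bl.size();
    for (int i = 0; i < nbo; i++) {
      List b = bl[i];
      Bone bo;
      bo.body = as<int>(b["body"]);
      bo.frac = as<double>(b["frac"]);
      bo.A = as<double>(b["A"]); bo.I = as<double>(b["I"]);
      bo.c = as<double>(b["c"]); bo.fail = as<double>(b["fail"]);
      // descendants of bo.body
      for (int k = 0; k < nb; k++) {
        int p = parent[k];
        bool desc = false;
        while (p >= 0) { if (p == bo.body) { desc = true; break; } p = parent[p]; }
        if (desc) bo.subtree.push_back(k);
      }
      bones.push_back(bo);
    }

    ang.resize(nb); ca.resize(nb); sa.resize(nb);
    pos.resize(nb); vel.resize(nb); acc.resize(nb); acom.resize(nb);
    comw.resize(nb); velcom.resize(nb);
    om.resize(nb); al.resize(nb);
    Facc.resize(nb); Macc.resize(nb);
    Mmat.resize(n * n); Cvec.resize(n); Q.resize(n); qdd_ws.resize(n);
    chain.resize(nb);
    for (int i = 0; i < nb; i++) {
      int b = i;
      while (parent[b] >= 0) { chain[i].push_back(3 + (b - 1)); b = parent[b]; }
    }
    mus_F.assign(na, 0); mus_vce.assign(na, 0); mus_lmtu.assign(na, 0);
    mus_Fce.assign(na, 0); mus_Fse.assign(na, 0); mus_Fpe.assign(na, 0);
    mus_vmtu.assign(na, 0); mus_act.assign(na, 0);
    bone_stress_ws.assign(nbo, 0);
  }

  void fk(const double* q) {
    ang[0] = q[2];
    pos[0] = v2(q[0], q[1]);
    // bodies are ordered parent-first
    for (int i = 1; i < nb; i++) {
      int p = parent[i];
      ang[i] = ang[p] + offset[i] + q[3 + (i - 1)];
    }
    for (int i = 0; i < nb; i++) { ca[i] = std::cos(ang[i]); sa[i] = std::sin(ang[i]); }
    for (int i = 1; i < nb; i++) {
      int p = parent[i];
      V2 r = v2(ca[p] * ancx[i] - sa[p] * ancz[i],
                sa[p] * ancx[i] + ca[p] * ancz[i]);
      pos[i] = pos[p] + r;
    }
    for (int i = 0; i < nb; i++) {
      V2 rc = v2(ca[i] * comx[i] - sa[i] * comz[i],
                 sa[i] * comx[i] + ca[i] * comz[i]);
      comw[i] = pos[i] + rc;
    }
  }

  void kin_vel(const double* q, const double* qd) {
    om[0] = qd[2];
    vel[0] = v2(qd[0], qd[1]);
    for (int i = 1; i < nb; i++) {
      int p = parent[i];
      om[i] = om[p] + qd[3 + (i - 1)];
      V2 r = pos[i] - pos[p];
      vel[i] = vel[p] + omcross(om[p], r);
    }
    for (int i = 0; i < nb; i++)
      velcom[i] = vel[i] + omcross(om[i], comw[i] - pos[i]);
  }

  V2 world_pt(int b, double lx, double lz) const {
    return pos[b] + v2(ca[b] * lx - sa[b] * lz, sa[b] * lx + ca[b] * lz);
  }
  V2 vel_pt(int b, double lx, double lz) const {
    V2 r = v2(ca[b] * lx - sa[b] * lz, sa[b] * lx + ca[b] * lz);
    return vel[b] + omcross(om[b], r);
  }

  // Recursive Newton-Euler: generalized force required to produce qdd at
  // state (q, qd) under gravity gz (pass 0 for mass-matrix columns).
  // Assumes fk() has been called for q.  Does not disturb vel/om.
  void rne(const double* qd, const double* qdd, double gz, double* out) {
    static thread_local std::vector<double> oml, all;
    static thread_local std::vector<V2> vl, al2, acl;
    oml.resize(nb); all.resize(nb); vl.resize(nb); al2.resize(nb); acl.resize(nb);
    oml[0] = qd[2]; all[0] = qdd[2];
    vl[0] = v2(qd[0], qd[1]); al2[0] = v2(qdd[0], qdd[1]);
    for (int i = 1; i < nb; i++) {
      int p = parent[i];
      V2 r = pos[i] - pos[p];
      oml[i] = oml[p] + qd[3 + (i - 1)];
      all[i] = all[p] + qdd[3 + (i - 1)];
      vl[i] = vl[p] + omcross(oml[p], r);
      al2[i] = al2[p] + omcross(all[p], r) - (oml[p] * oml[p]) * r;
    }
    for (int i = 0; i < nb; i++) {
      V2 rc = comw[i] - pos[i];
      acl[i] = al2[i] + omcross(all[i], rc) - (oml[i] * oml[i]) * rc;
    }
    for (int i = 0; i < nb; i++) {
      Facc[i] = v2(mass[i] * acl[i].x, mass[i] * (acl[i].z + gz));
      Macc[i] = moi[i] * all[i] + cross(comw[i] - pos[i], Facc[i]);
    }
    for (int i = nb - 1; i >= 1; i--) {
      int p = parent[i];
      out[3 + (i - 1)] = Macc[i];
      Facc[p] = Facc[p] + Facc[i];
      Macc[p] += Macc[i] + cross(pos[i] - pos[p], Facc[i]);
    }
    out[0] = Facc[0].x; out[1] = Facc[0].z; out[2] = Macc[0];
  }

  // dense symmetric positive-definite solve (Cholesky, in place on copies)
  void chol_solve(std::vector<double>& A, double* b, double* x) {
    int m = n;
    for (int i = 0; i < m; i++) {
      for (int j = 0; j <= i; j++) {
        double s = A[i * m + j];
        for (int k = 0; k < j; k++) s -= A[i * m + k] * A[j * m + k];
        if (i == j) {
          A[i * m + i] = std::sqrt(s > 1e-12 ? s : 1e-12);
        } else {
          A[i * m + j] = s / A[j * m + j];
        }
      }
    }
    for (int i = 0; i < m; i++) {
      double s = b[i];
      for (int k = 0; k < i; k++) s -= A[i * m + k] * x[k];
      x[i] = s / A[i * m + i];
    }
    for (int i = m - 1; i >= 0; i--) {
      double s = x[i];
      for (int k = i + 1; k < m; k++) s -= A[k * m + i] * x[k];
      x[i] = s / A[i * m + i];
    }
  }

  void apply_point_force(int body, V2 P, V2 F, double lx, double lz,
                         double* Qv, bool record_pf) {
    Qv[0] += F.x; Qv[1] += F.z;
    Qv[2] += cross(P - pos[0], F);
    for (size_t k = 0; k < chain[body].size(); k++) {
      int qi = chain[body][k];
      int jb = qi - 3 + 1;  // body whose joint this is
      Qv[qi] += cross(P - pos[jb], F);
    }
    if (record_pf) {
      PointForce rec; rec.body = body; rec.lx = lx; rec.lz = lz;
      rec.P = P; rec.F = F;
      pf.push_back(rec);
    }
  }

  std::vector<V2> geo_Pw, geo_Vw;           // path-point workspace
  std::vector<PointForce> geo_uf;           // unit-force workspace

  // Geometric path of muscle m at the current fk(): returns length, and
  // (optionally) unit-tension point forces and the path shortening rate.
  double muscle_geometry(const Muscle& mu, bool with_vel, double* vmtu,
                         std::vector<PointForce>* unit_forces) {
    double L = 0;
    double vrate = 0;  // dL/dt
    int np = mu.body.size();
    geo_Pw.resize(np); geo_Vw.resize(np);
    std::vector<V2>& Pw = geo_Pw;
    std::vector<V2>& Vw = geo_Vw;
    for (int k = 0; k < np; k++) {
      Pw[k] = world_pt(mu.body[k], mu.px[k], mu.pz[k]);
      if (with_vel) Vw[k] = vel_pt(mu.body[k], mu.px[k], mu.pz[k]);
    }
    for (int g = 0; g < np - 1; g++) {
      const Wrap* wr = 0;
      for (size_t w = 0; w < mu.wraps.size(); w++)
        if (mu.wraps[w].after == g) wr = &mu.wraps[w];
      V2 A = Pw[g], B = Pw[g + 1];
      bool wrapped = false;
      if (wr) {
        V2 C = world_pt(wr->body, wr->cx, wr->cz);
        double r = wr->r;
        // engage if the straight segment passes within r of the centre
        V2 ab = B - A;
        double t = dot(C - A, ab) / (dot(ab, ab) + 1e-30);
        if (t < 0) t = 0; if (t > 1) t = 1;
        double dseg = norm(A + t * ab - C);
        double dA = norm(A - C), dB = norm(B - C);
        if (dseg < r && dA > r * 1.0001 && dB > r * 1.0001) {
          int s = wr->dir;
          double phiA = std::atan2(A.z - C.z, A.x - C.x);
          double phiB = std::atan2(B.z - C.z, B.x - C.x);
          double bA = std::acos(std::min(1.0, r / dA));
          double bB = std::acos(std::min(1.0, r / dB));
          double th1 = phiA + s * bA;
          double th2 = phiB - s * bB;
          double darc = s * (th2 - th1);
          while (darc < 0) darc += 2 * M_PI;
          while (darc >= 2 * M_PI) darc -= 2 * M_PI;
          if (darc > 0 && darc < M_PI) {
            V2 T1 = C + v2(r * std::cos(th1), r * std::sin(th1));
            V2 T2 = C + v2(r * std::cos(th2), r * std::sin(th2));
            double l1 = norm(T1 - A), l2 = norm(B - T2);
            L += l1 + r * darc + l2;
            wrapped = true;
            if (unit_forces || with_vel) {
              V2 u1 = (1.0 / (l1 + 1e-30)) * (T1 - A);   // A -> T1
              V2 u2 = (1.0 / (l2 + 1e-30)) * (B - T2);   // T2 -> B
              // pulls: on A's body toward T1; on B's body toward T2;
              // resultant on wrap body at the centre.
              if (unit_forces) {
                PointForce f1; f1.body = mu.body[g];
                f1.lx = mu.px[g]; f1.lz = mu.pz[g]; f1.P = A; f1.F = u1;
                unit_forces->push_back(f1);
                PointForce f2; f2.body = mu.body[g + 1];
                f2.lx = mu.px[g + 1]; f2.lz = mu.pz[g + 1]; f2.P = B;
                f2.F = (-1.0) * u2;
                unit_forces->push_back(f2);
                PointForce fw; fw.body = wr->body; fw.lx = wr->cx;
                fw.lz = wr->cz; fw.P = C; fw.F = (-1.0) * u1 + u2;
                unit_forces->push_back(fw);
              }
              if (with_vel) {
                V2 Vc = vel_pt(wr->body, wr->cx, wr->cz);
                // dL/dt = -sum(unit force . point velocity)
                vrate -= dot(u1, Vw[g]) + dot((-1.0) * u2, Vw[g + 1]) +
                         dot((-1.0) * u1 + u2, Vc);
              }
            }
          }
        }
      }
      if (!wrapped) {
        double l = norm(B - A);
        L += l;
        if (unit_forces || with_vel) {
          V2 u = (1.0 / (l + 1e-30)) * (B - A);
          if (unit_forces) {
            PointForce f1; f1.body = mu.body[g]; f1.lx = mu.px[g];
            f1.lz = mu.pz[g]; f1.P = A; f1.F = u;
            unit_forces->push_back(f1);
            PointForce f2; f2.body = mu.body[g + 1]; f2.lx = mu.px[g + 1];
            f2.lz = mu.pz[g + 1]; f2.P = B; f2.F = (-1.0) * u;
            unit_forces->push_back(f2);
          }
          if (with_vel) vrate -= dot(u, Vw[g]) + dot((-1.0) * u, Vw[g + 1]);
        }
      }
    }
    if (with_vel) *vmtu = -vrate;  // shortening rate, positive = shortening
    return L;
  }

  // Hill machinery: given MTU length/shortening-rate, activation and CE
  // length, produce MTU force and CE shortening rate (m/s, positive =
  // shortening).  `tl` is the (possibly gene-scaled) tendon slack length.
  void muscle_force(const Muscle& mu, double tl, double lmtu, double vmtu,
                    double act, double lce_in, double* F, double* vce,
                    double* lce_used, double* Fce, double* Fse, double* Fpe) {
    double lce = lce_in;
    bool rigid = tl < 1e-7;
    if (rigid) {
      lce = lmtu;
      double v = vmtu;
      double fpe = pe_force(lce, mu.lopt, mu.fmax, mu.pekrel, mu.peeng);
      double fce = act * mu.fmax * fl_curve(lce, mu.lopt, mu.flw) *
                   fv_curve(v / mu.vmax_abs, mu.fva);
      *F = fce + fpe; *vce = v; *lce_used = lce;
      *Fce = fce; *Fse = *F; *Fpe = fpe;
      return;
    }
    double lse = lmtu - lce;
    double strain = (lse - tl) / tl;
    double fse = strain > 0 ? mu.fmax * strain / mu.sestr : 0.0;
    double fpe = pe_force(lce, mu.lopt, mu.fmax, mu.pekrel, mu.peeng);
    double freq = fse - fpe;  // force the CE must supply
    double f0 = act * mu.fmax * fl_curve(lce, mu.lopt, mu.flw);
    double v;
    if (freq <= 0) {
      // slack or PE-dominated: CE shortens at its maximum rate
      v = mu.vmax_abs;
    } else if (f0 < 1e-9) {
      v = -mu.vmax_abs;  // overloaded inactive fibre lengthens
    } else {
      double r = freq / f0;
      if (r < 1.0) {
        double u = mu.fva * (1.0 - r) / (mu.fva + r);
        v = u * mu.vmax_abs;
      } else {
        double u = (r - 1.0) / 0.5;  // shallow eccentric inversion slope
        if (u > 1.0) u = 1.0;
        v = -u * mu.vmax_abs;
      }
    }
    *F = fse; *vce = v; *lce_used = lce;
    *Fce = freq > 0 ? freq : 0.0; *Fse = fse; *Fpe = fpe;
  }

  // Full derivative evaluation; fills qdd_ws, dlce, caches point forces
  // and per-muscle outputs.
  void deriv(const double* q, const double* qd, const double* lce,
             const double* act, const double* tscale, double* qdd,
             double* dlce, bool cache_pf) {
    fk(q);
    kin_vel(q, qd);
    pf.clear();
    for (int i = 0; i < n; i++) Q[i] = 0;
    grf_x = 0; grf_z = 0;

    // muscles
    for (int mi = 0; mi < na; mi++) {
      const Muscle& mu = muscles[mi];
      double tl = mu.tl * tscale[mi];
      geo_uf.clear();
      double vmtu = 0;
      double L = muscle_geometry(mu, true, &vmtu, &geo_uf);
      double F, vce, lceu, fce, fse, fpe;
      muscle_force(mu, tl, L, vmtu, act[mi], lce[mi], &F, &vce, &lceu,
                   &fce, &fse, &fpe);
      mus_F[mi] = F; mus_vce[mi] = vce; mus_lmtu[mi] = L;
      mus_Fce[mi] = fce; mus_Fse[mi] = fse; mus_Fpe[mi] = fpe;
      mus_vmtu[mi] = vmtu; mus_act[mi] = act[mi];
      dlce[mi] = (tl < 1e-7) ? 0.0 : -vce;
      for (size_t k = 0; k < geo_uf.size(); k++)
        apply_point_force(geo_uf[k].body, geo_uf[k].P, F * geo_uf[k].F,
                          geo_uf[k].lx, geo_uf[k].lz, &Q[0], cache_pf);
    }

    // contacts
    for (int ci = 0; ci < nc; ci++) {
      const Contact& ct = contacts[ci];
      V2 P = world_pt(ct.body, ct.px, ct.pz);
      if (P.z >= 0) continue;
      V2 v = vel_pt(ct.body, ct.px, ct.pz);
      double Fz = -ct.k * P.z - ct.c * v.z;
      if (Fz < 0) continue;  // unilateral: no adhesion
      double Fx = -ct.mu * Fz * std::tanh(v.x / 0.01);
      apply_point_force(ct.body, P, v2(Fx, Fz), ct.px, ct.pz, &Q[0], cache_pf);
      grf_x += Fx; grf_z += Fz;
    }

    // soft joint limits
    for (int j = 0; j < nj; j++) {
      double qj = q[3 + j], qdj = qd[3 + j], tau = 0;
      if (qj > jhi[j]) tau = -jk[j] * (qj - jhi[j]) - jc[j] * qdj;
      else if (qj < jlo[j]) tau = -jk[j] * (qj - jlo[j]) - jc[j] * qdj;
      Q[3 + j] += tau;
    }

    // dynamics: M qdd = Q - C
    static thread_local std::vector<double> zero, ej, col, A;
    zero.assign(n, 0.0); ej.assign(n, 0.0); col.resize(n); A.resize(n * n);
    rne(qd, &zero[0], grav, &Cvec[0]);
    for (int j = 0; j < n; j++) {
      ej[j] = 1.0;
      rne(&zero[0], &ej[0], 0.0, &col[0]);
      ej[j] = 0.0;
      for (int i = 0; i < n; i++) A[i * n + j] = col[i];
    }
    static thread_local std::vector<double> rhs;
    rhs.resize(n);
    for (int i = 0; i < n; i++) rhs[i] = Q[i] - Cvec[i];
    if (fixed_base) {
      // pin the base: identity rows/cols for the base coordinates
      for (int i = 0; i < 3; i++) {
        for (int j = 0; j < n; j++) { A[i * n + j] = 0; A[j * n + i] = 0; }
        A[i * n + i] = 1.0;
        rhs[i] = 0;
      }
    }
    chol_solve(A, &rhs[0], qdd);
  }

  // forward acceleration pass for bone stress (fk/kin_vel assumed current)
  void forward_accel(const double* qd, const double* qdd) {
    al[0] = qdd[2];
    acc[0] = v2(qdd[0], qdd[1]);
    for (int i = 1; i < nb; i++) {
      int p = parent[i];
      V2 r = pos[i] - pos[p];
      al[i] = al[p] + qdd[3 + (i - 1)];
      acc[i] = acc[p] + omcross(al[p], r) - (om[p] * om[p]) * r;
    }
    for (int i = 0; i < nb; i++) {
      V2 rc = comw[i] - pos[i];
      acom[i] = acc[i] + omcross(al[i], rc) - (om[i] * om[i]) * rc;
    }
  }

  // peak compressive midshaft stress per bone section; requires deriv()
  // to have cached point forces (cache_pf = true) and forward_accel().
  void bone_stresses(double* out) {
    V2 g = v2(0, -grav);
    for (int bi = 0; bi < nbo; bi++) {
      const Bone& bo = bones[bi];
      int s = bo.body;
      double cut_x = bo.frac * seglen[s];
      V2 Xc = world_pt(s, cut_x, 0);
      V2 axis = v2(ca[s], sa[s]);
      V2 Fnet = v2(0, 0);
      double Mnet = 0;
      // distal half of the sectioned segment (uniform split)
      double mh = mass[s] * (1.0 - bo.frac);
      double hx = (bo.frac + 1.0) * 0.5 * seglen[s];
      double lh = (1.0 - bo.frac) * seglen[s];
      double Ih = mh * lh * lh / 12.0;
      V2 rc = v2(ca[s] * hx - sa[s] * 0, sa[s] * hx + ca[s] * 0);
      V2 ch = pos[s] + rc;
      V2 ah = acc[s] + omcross(al[s], rc) - (om[s] * om[s]) * rc;
      V2 fi = v2(mh * (ah.x - g.x), mh * (ah.z - g.z));
      Fnet = Fnet + fi;
      Mnet += Ih * al[s] + cross(ch - Xc, fi);
      // descendant bodies in full
      for (size_t k = 0; k < bo.subtree.size(); k++) {
        int b = bo.subtree[k];
        V2 fb = v2(mass[b] * (acom[b].x - g.x), mass[b] * (acom[b].z - g.z));
        Fnet = Fnet + fb;
        Mnet += moi[b] * al[b] + cross(comw[b] - Xc, fb);
      }
      // subtract external point forces applied distal to the cut
      for (size_t k = 0; k < pf.size(); k++) {
        const PointForce& p = pf[k];
        bool distal = false;
        if (p.body == s) distal = p.lx > cut_x;
        else {
          for (size_t q = 0; q < bo.subtree.size(); q++)
            if (bo.subtree[q] == p.body) { distal = true; break; }
        }
        if (distal) {
          Fnet = Fnet - p.F;
          Mnet -= cross(p.P - Xc, p.F);
        }
      }
      double axial = std::fabs(dot(Fnet, axis));
      out[bi] = axial / bo.A + std::fabs(Mnet) * bo.c / bo.I;
    }
  }

  double com_z() {
    double z = 0;
    for (int i = 0; i < nb; i++) z += mass[i] * comw[i].z;
    return z / total_mass;
  }
  double com_x() {
    double x = 0;
    for (int i = 0; i < nb; i++) x += mass[i] * comw[i].x;
    return x / total_mass;
  }
  V2 com_vel() {
    V2 v = v2(0, 0);
    for (int i = 0; i < nb; i++) v = v + mass[i] * velcom[i];
    return (1.0 / total_mass) * v;
  }
  double kinetic() {
    double e = 0;
    for (int i = 0; i < nb; i++)
      e += 0.5 * mass[i] * dot(velcom[i], velcom[i]) +
           0.5 * moi[i] * om[i] * om[i];
    return e;
  }
  double potential() {
    double e = 0;
    for (int i = 0; i < nb; i++) e += mass[i] * grav * comw[i].z;
    return e;
  }
};

// piecewise-constant activation lookup
inline double act_at(const double* dur, const double* lev, int np, double t) {
  double acc = 0;
  for (int p = 0; p < np; p++) {
    acc += dur[p];
    if (t < acc) return lev[p];
  }
  return 0.0;
}

}  // namespace

// [[Rcpp::export]]
SEXP engine_create(List spec) {
  Engine* e = new Engine(spec);
  XPtr<Engine> p(e, true);
  return p;
}

// [[Rcpp::export]]
NumericMatrix engine_path_lengths(SEXP ptr, NumericMatrix poses_rad) {
  XPtr<Engine> e(ptr);
  int np = poses_rad.nrow();
  NumericMatrix out(np, e->na);
  std::vector<double> q(e->n, 0.0);
  for (int r = 0; r < np; r++) {
    for (int j = 0; j < e->nj; j++) q[3 + j] = poses_rad(r, j);
    e->fk(&q[0]);
    for (int m = 0; m < e->na; m++) {
      double v;
      out(r, m) = e->muscle_geometry(e->muscles[m], false, &v, 0);
    }
  }
  return out;
}

// [[Rcpp::export]]
List engine_fk(SEXP ptr, NumericVector q) {
  XPtr<Engine> e(ptr);
  std::vector<double> qq(q.begin(), q.end());
  e->fk(&qq[0]);
  NumericMatrix bp(e->nb, 2), bc(e->nb, 2);
  NumericVector ba(e->nb);
  for (int i = 0; i < e->nb; i++) {
    bp(i, 0) = e->pos[i].x; bp(i, 1) = e->pos[i].z;
    bc(i, 0) = e->comw[i].x; bc(i, 1) = e->comw[i].z;
    ba[i] = e->ang[i];
  }
  NumericMatrix cp(e->nc, 2);
  for (int c = 0; c < e->nc; c++) {
    V2 P = e->world_pt(e->contacts[c].body, e->contacts[c].px, e->contacts[c].pz);
    cp(c, 0) = P.x; cp(c, 1) = P.z;
  }
  return List::create(_["body_pos"] = bp, _["body_angle"] = ba,
                      _["body_com"] = bc, _["contact_pos"] = cp,
                      _["com"] = NumericVector::create(e->com_x(), e->com_z()));
}

// [[Rcpp::export]]
double engine_hill_force(List params, double act, double lce_mm,
                         double vce_Ls) {
  // standalone Hill fibre force (CE + PE), used to cross-check the R
  // implementation against the engine's internal curves
  double fmax = as<double>(params["fmax"]);
  double lopt = as<double>(params["lopt_mm"]);
  double a = as<double>(params["fv_shape"]);
  double w = as<double>(params["fl_width"]);
  double krel = as<double>(params["pe_k_rel"]);
  double eng = as<double>(params["pe_engage"]);
  double vmax = as<double>(params["vmax"]);
  double fce = act * fmax * fl_curve(lce_mm, lopt, w) *
               fv_curve(vce_Ls / vmax, a);
  return fce + pe_force(lce_mm, lopt, fmax, krel, eng);
}

// [[Rcpp::export]]
List engine_simulate(SEXP ptr, NumericVector q0, NumericVector qd0,
                     NumericMatrix durations, NumericMatrix levels,
                     NumericVector tendon_scale, double duration, double dt,
                     double record_dt, std::string integrator,
                     bool check_stress, bool record) {
  XPtr<Engine> e(ptr);
  int n = e->n, na = e->na, nbo = e->nbo, np = durations.ncol();
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> qd(qd0.begin(), qd0.end());
  std::vector<double> lce(na), act(na), dlce(na), qdd(n);
  std::vector<double> tsc(tendon_scale.begin(), tendon_scale.end());
  bool rk4 = integrator == "rk4";

  // initial CE lengths: strain-free series element at the start pose
  e->fk(&q[0]);
  for (int m = 0; m < na; m++) {
    const Muscle& mu = e->muscles[m];
    double v;
    double L = e->muscle_geometry(mu, false, &v, 0);
    double tl = mu.tl * tsc[m];
    if (tl < 1e-7) lce[m] = L;
    else {
      double l = L - tl;
      double lo = 0.05 * mu.lopt, hi = 1.8 * mu.lopt;
      if (l < lo) l = lo;
      if (l > hi) l = hi;
      lce[m] = l;
    }
  }

  int nsteps = (int)std::ceil(duration / dt);
  int rec_every = record_dt > 0 ? std::max(1, (int)std::lround(record_dt / dt)) : nsteps + 1;
  int nrec = record ? nsteps / rec_every + 2 : 0;

  int nj = e->nj;
  int base_cols = 10;  // time com_x com_z com_vx com_vz grf_x grf_z impz ke pe
  int ncol = record ? base_cols + 2 * (3 + nj) + 8 * na + nbo : 0;
  NumericMatrix traj(record ? nrec : 0, ncol);

  std::vector<double> wce(na, 0), wse(na, 0), wpe(na, 0), wmtu(na, 0);
  double imp_z = 0;
  double max_com = -1e300, t_max_com = 0;
  bool stress_exceeded = false, blowup = false;
  double stress_time = NA_REAL, blowup_time = NA_REAL, end_time = 0;
  int irow = 0;

  std::vector<double> stress(nbo, 0.0);

  // scratch for RK4
  std::vector<double> k1q(n), k1v(n), k2q(n), k2v(n), k3q(n), k3v(n),
      k4q(n), k4v(n), ql(n), qdl(n), lcel(na), d1(na), d2(na), d3(na), d4(na),
      qdd2(n), qdd3(n), qdd4(n);

  for (int s = 0; s <= nsteps; s++) {
    double t = s * dt;
    for (int m = 0; m < na; m++)
      act[m] = act_at(&durations(m, 0), &levels(m, 0), np, t);
    // force/acceleration evaluation at current state
    e->deriv(&q[0], &qd[0], &lce[0], &act[0], &tsc[0],
             &qdd[0], &dlce[0], true);

    double cz = e->com_z();
    if (cz > max_com) { max_com = cz; t_max_com = t; }

    if (check_stress && nbo > 0) {
      e->forward_accel(&qd[0], &qdd[0]);
      e->bone_stresses(&stress[0]);
      for (int b = 0; b < nbo; b++)
        if (stress[b] > e->bones[b].fail) {
          stress_exceeded = true;
          stress_time = t;
        }
    }

    bool bad = false;
    for (int i = 0; i < n; i++)
      if (!std::isfinite(q[i]) || !std::isfinite(qd[i]) ||
          std::fabs(qd[i]) > 1e6) bad = true;
    if (bad) { blowup = true; blowup_time = t; }

    if (record && (s % rec_every == 0 || s == nsteps || stress_exceeded ||
                   blowup)) {
      V2 cv = e->com_vel();
      int c = 0;
      traj(irow, c++) = t;
      traj(irow, c++) = e->com_x(); traj(irow, c++) = cz;
      traj(irow, c++) = cv.x; traj(irow, c++) = cv.z;
      traj(irow, c++) = e->grf_x; traj(irow, c++) = e->grf_z;
      traj(irow, c++) = imp_z;
      traj(irow, c++) = e->kinetic(); traj(irow, c++) = e->potential();
      for (int i = 0; i < n; i++) traj(irow, c++) = q[i];
      for (int i = 0; i < n; i++) traj(irow, c++) = qd[i];
      for (int m = 0; m < na; m++) {
        traj(irow, c++) = act[m];
        traj(irow, c++) = e->mus_F[m];
        traj(irow, c++) = (e->muscles[m].tl * tsc[m] < 1e-7 ? e->mus_lmtu[m]
                                                            : lce[m]) * 1000.0;
        traj(irow, c++) = e->mus_vce[m] / e->muscles[m].lopt;  // L s^-1
        traj(irow, c++) = wce[m];
        traj(irow, c++) = wse[m];
        traj(irow, c++) = wpe[m];
        traj(irow, c++) = wmtu[m];
      }
      for (int b = 0; b < nbo; b++) traj(irow, c++) = stress[b];
      irow++;
    }

    end_time = t;
    if (stress_exceeded || blowup || s == nsteps) break;

    // accumulators (first-order, at the pre-step evaluation)
    imp_z += e->grf_z * dt;
    for (int m = 0; m < na; m++) {
      double vse = e->mus_vmtu[m] - e->mus_vce[m];  // SE shortening rate
      wce[m] += e->mus_Fce[m] * e->mus_vce[m] * dt;
      wpe[m] += e->mus_Fpe[m] * e->mus_vce[m] * dt;
      wse[m] += e->mus_Fse[m] * vse * dt;
      wmtu[m] += e->mus_F[m] * e->mus_vmtu[m] * dt;
    }

    if (!rk4) {
      for (int i = 0; i < n; i++) { qd[i] += qdd[i] * dt; q[i] += qd[i] * dt; }
      for (int m = 0; m < na; m++) lce[m] += dlce[m] * dt;
    } else {
      // classical RK4 on (q, qd, lce); k1 already evaluated
      for (int i = 0; i < n; i++) { k1q[i] = qd[i]; k1v[i] = qdd[i]; }
      for (int m = 0; m < na; m++) d1[m] = dlce[m];
      for (int i = 0; i < n; i++) { ql[i] = q[i] + 0.5 * dt * k1q[i];
                                    qdl[i] = qd[i] + 0.5 * dt * k1v[i]; }
      for (int m = 0; m < na; m++) lcel[m] = lce[m] + 0.5 * dt * d1[m];
      e->deriv(&ql[0], &qdl[0], &lcel[0], &act[0], &tsc[0], &qdd2[0], &d2[0], false);
      for (int i = 0; i < n; i++) { k2q[i] = qdl[i]; k2v[i] = qdd2[i]; }
      for (int i = 0; i < n; i++) { ql[i] = q[i] + 0.5 * dt * k2q[i];
                                    qdl[i] = qd[i] + 0.5 * dt * k2v[i]; }
      for (int m = 0; m < na; m++) lcel[m] = lce[m] + 0.5 * dt * d2[m];
      e->deriv(&ql[0], &qdl[0], &lcel[0], &act[0], &tsc[0], &qdd3[0], &d3[0], false);
      for (int i = 0; i < n; i++) { k3q[i] = qdl[i]; k3v[i] = qdd3[i]; }
      for (int i = 0; i < n; i++) { ql[i] = q[i] + dt * k3q[i];
                                    qdl[i] = qd[i] + dt * k3v[i]; }
      for (int m = 0; m < na; m++) lcel[m] = lce[m] + dt * d3[m];
      e->deriv(&ql[0], &qdl[0], &lcel[0], &act[0], &tsc[0], &qdd4[0], &d4[0], false);
      for (int i = 0; i < n; i++) { k4q[i] = qdl[i]; k4v[i] = qdd4[i]; }
      for (int i = 0; i < n; i++) {
        q[i] += dt / 6.0 * (k1q[i] + 2 * k2q[i] + 2 * k3q[i] + k4q[i]);
        qd[i] += dt / 6.0 * (k1v[i] + 2 * k2v[i] + 2 * k3v[i] + k4v[i]);
      }
      for (int m = 0; m < na; m++)
        lce[m] += dt / 6.0 * (d1[m] + 2 * d2[m] + 2 * d3[m] + d4[m]);
    }
  }

  List out = List::create(
      _["max_com_z"] = max_com,
      _["t_max_com"] = t_max_com,
      _["stress_exceeded"] = stress_exceeded,
      _["stress_time"] = stress_time,
      _["blowup"] = blowup,
      _["blowup_time"] = blowup_time,
      _["end_time"] = end_time,
      _["final_q"] = NumericVector(q.begin(), q.end()),
      _["final_qd"] = NumericVector(qd.begin(), qd.end()));
  if (record) {
    out["trajectory"] = traj;
    out["nrec"] = irow;
  }
  return out;
}
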