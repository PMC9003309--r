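// Hot kernels for the windowed pose + calibration estimator:
//  - strapdown dead-reckoning of gyro data,
//  - per-interval preintegration of raw measurements between keyframes,
//  - stacked whitened residual vector and its sparse Jacobian (numeric
//    central differences per residual block; blocks touch few coordinates,
//    so differencing is exact-sparsity and cheap).
//
// Conventions match the R side: quaternions (w,x,y,z) map sensor frame ->
// world; world z is up, gravity (0,0,-g); local rotation perturbations are
// applied on the right: R <- R * Exp(dtheta).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline vec4 qmul(const vec4& a, const vec4& b) {
  vec4 r;
  r(0) = a(0)*b(0) - a(1)*b(1) - a(2)*b(2) - a(3)*b(3);
  r(1) = a(0)*b(1) + a(1)*b(0) + a(2)*b(3) - a(3)*b(2);
  r(2) = a(0)*b(2) - a(1)*b(3) + a(2)*b(0) + a(3)*b(1);
  r(3) = a(0)*b(3) + a(1)*b(2) - a(2)*b(1) + a(3)*b(0);
  return r;
}

static inline vec4 qconjq(const vec4& q) {
  vec4 r = {q(0), -q(1), -q(2), -q(3)};
  return r;
}

static inline vec4 qexpv(const vec3& phi) {
  double ang = norm(phi);
  double half = 0.5 * ang;
  double s = (ang > 1e-8) ? std::sin(half) / ang : 0.5 - ang * ang / 48.0;
  vec4 r = {std::cos(half), phi(0) * s, phi(1) * s, phi(2) * s};
  return r;
}

static inline vec3 qlogv(const vec4& qin) {
  vec4 q = qin;
  if (q(0) < 0) q = -q;
  double vn = std::sqrt(q(1)*q(1) + q(2)*q(2) + q(3)*q(3));
  double w = std::min(q(0), 1.0);
  double ang = 2.0 * std::atan2(vn, w);
  double k = (vn > 1e-12) ? ang / vn : 2.0 / std::max(w, 1e-300);
  vec3 r = {q(1) * k, q(2) * k, q(3) * k};
  return r;
}

// rotate v by R(q)
static inline vec3 qrot(const vec4& q, const vec3& v) {
  vec3 u = {q(1), q(2), q(3)};
  vec3 uv = cross(u, v);
  return v + 2.0 * q(0) * uv + 2.0 * cross(u, uv);
}

static inline vec3 qrotT(const vec4& q, const vec3& v) {
  return qrot(qconjq(q), v);
}

static inline double qyaw(const vec4& q) {
  // atan2(R21, R11) of the rotation matrix
  double r21 = 2.0 * (q(1)*q(2) + q(0)*q(3));
  double r11 = 1.0 - 2.0 * (q(2)*q(2) + q(3)*q(3));
  return std::atan2(r21, r11);
}

// ---------------------------------------------------------------------------

//' @name wk_deadreckon
//' Integrate gyro samples into an orientation sequence (internal)
// [[Rcpp::export(name = ".wk_deadreckon")]]
arma::mat wk_deadreckon(const arma::vec& q0, const arma::mat& gyroM,
                        double dt) {
  uword n = gyroM.n_rows;
  mat out(n, 4);
  vec4 q = {q0(0), q0(1), q0(2), q0(3)};
  q /= norm(q);
  out.row(0) = q.t();
  for (uword k = 0; k + 1 < n; ++k) {
    vec3 w = gyroM.row(k).t() * dt;
    q = qmul(q, qexpv(w));
    q /= norm(q);
    out.row(k + 1) = q.t();
  }
  return out;
}

struct Preint { vec4 dq; vec3 dv; vec3 dp; };

static Preint preintegrate(const mat& gyroM, const mat& accelM, uword i0,
                           uword m, double dt, const vec3& bg,
                           const vec3& ba) {
  Preint P;
  P.dq = {1, 0, 0, 0};
  P.dv.zeros(); P.dp.zeros();
  for (uword j = 0; j < m; ++j) {
    P.dp += P.dv * dt;
    P.dv += qrot(P.dq, accelM.row(i0 + j).t() - ba) * dt;
    P.dq = qmul(P.dq, qexpv((gyroM.row(i0 + j).t() - bg) * dt));
  }
  P.dq /= norm(P.dq);
  return P;
}

static void inertialRes(const vec4& qk, const vec3& vk, const vec3& pk,
                        const vec4& qk1, const vec3& vk1, const vec3& pk1,
                        const Preint& P, double Dt, double dt2S1,
                        const vec3& g, double sR, double sv, double sp,
                        double* out) {
  vec4 qrel = qmul(qconjq(P.dq), qmul(qconjq(qk), qk1));
  vec3 rR = qlogv(qrel) / sR;
  vec3 rv = (qrotT(qk, vk1 - vk - g * Dt) - P.dv) / sv;
  vec3 rp = (qrotT(qk, pk1 - pk - vk * Dt - g * dt2S1) - P.dp) / sp;
  for (int i = 0; i < 3; ++i) {
    out[i] = rR(i); out[3 + i] = rv(i); out[6 + i] = rp(i);
  }
}

// perturb one local coordinate of an inertial block:
// which = 0 -> keyframe k, 1 -> keyframe k+1; c in 0..8 = theta, v, p
static inline void applyStatePert(vec4& qa, vec3& va, vec3& pa, vec4& qb,
                                  vec3& vb, vec3& pb, int which, int c,
                                  double h) {
  vec3 e = {0, 0, 0};
  if (c < 3) {
    e(c) = h;
    if (which == 0) qa = qmul(qa, qexpv(e)); else qb = qmul(qb, qexpv(e));
  } else if (c < 6) {
    if (which == 0) va(c - 3) += h; else vb(c - 3) += h;
  } else {
    if (which == 0) pa(c - 6) += h; else pb(c - 6) += h;
  }
}

// perturb one local coordinate of a joint-center block:
// c: 0-2 thetaA, 3-5 pA, 6-8 thetaB, 9-11 pB, 12-14 sA, 15-17 sB
static inline void applyJcPert(vec4& qa, vec3& pa, vec4& qb, vec3& pb,
                               vec3& sa, vec3& sb, int c, double h) {
  vec3 e = {0, 0, 0};
  if (c < 3) { e(c) = h; qa = qmul(qa, qexpv(e)); }
  else if (c < 6) pa(c - 3) += h;
  else if (c < 9) { e(c - 6) = h; qb = qmul(qb, qexpv(e)); }
  else if (c < 12) pb(c - 9) += h;
  else if (c < 15) sa(c - 12) += h;
  else sb(c - 15) += h;
}

// perturb one local coordinate of a hinge block:
// c: 0-2 thetaA, 3-5 thetaB, 6-8 axisA, 9-11 axisB
static inline void applyHingePert(vec4& qa, vec4& qb, vec3& aa, vec3& ab,
                                  int c, double h) {
  vec3 e = {0, 0, 0};
  if (c < 3) { e(c) = h; qa = qmul(qa, qexpv(e)); }
  else if (c < 6) { e(c - 3) = h; qb = qmul(qb, qexpv(e)); }
  else if (c < 9) aa(c - 6) += h;
  else ab(c - 9) += h;
}

// helper: push a 9 (or nr) row residual-block jacobian column
static inline void pushCol(std::vector<int>& ti, std::vector<int>& tj,
                           std::vector<double>& tx, int row0, int col,
                           const double* rp, const double* rm, double inv2h,
                           int nr) {
  for (int i = 0; i < nr; ++i) {
    double v = (rp[i] - rm[i]) * inv2h;
    if (v != 0.0) {
      ti.push_back(row0 + i + 1);   // 1-based for R
      tj.push_back(col + 1);
      tx.push_back(v);
    }
  }
}

// [[Rcpp::export(name = ".wk_eval")]]
List wk_eval(List problem, List params, bool wantJac) {
  const int K = as<int>(problem["K"]);
  const int m = as<int>(problem["m"]);
  const double dt = as<double>(problem["dt"]);
  const int nS = 7;
  const double Dt = m * dt;
  const double S1 = 0.5 * m * (m - 1.0);
  const double dt2S1 = dt * dt * S1;
  const double grav = as<double>(problem["grav"]);
  const vec3 g = {0, 0, -grav};

  const double sigGyro = std::max(as<double>(problem["sigGyro"]), 1e-4);
  const double sigAccel = std::max(as<double>(problem["sigAccel"]), 1e-3);
  const double sR = sigGyro * dt * std::sqrt((double)m);
  const double sv = sigAccel * dt * std::sqrt((double)m);
  double sumsq = 0;  // sum_{k=0}^{m-1} k^2
  for (int k = 0; k < m; ++k) sumsq += (double)k * k;
  const double sp = sigAccel * dt * dt * std::sqrt(std::max(sumsq, 1.0));
  const double sigJc = as<double>(problem["sigJc"]);
  const double sigUnit = as<double>(problem["sigUnit"]);
  const vec sigHinge = as<vec>(problem["sigHinge"]);
  const ivec hingeUse = as<ivec>(problem["hingeUse"]);
  const imat joints = as<imat>(problem["joints"]);  // 6 x 6, 1-based ids
  const double sigGp = as<double>(problem["sigGp"]);
  const double sigGv = as<double>(problem["sigGv"]);
  const double sigGy = as<double>(problem["sigGy"]);
  const double sigBg = as<double>(problem["sigBgPrior"]);
  const double sigBa = as<double>(problem["sigBaPrior"]);
  const double sigJcPrior = as<double>(problem["sigJcPrior"]);
  const double sigAxPrior = as<double>(problem["sigAxPrior"]);
  const int gaugeSensor = as<int>(problem["gaugeSensor"]) - 1;

  List gyroL = problem["gyro"], accelL = problem["accel"];
  std::vector<mat> gyro(nS), accel(nS);
  for (int s = 0; s < nS; ++s) {
    gyro[s] = as<mat>(gyroL[s]);
    accel[s] = as<mat>(accelL[s]);
  }

  List qL = params["q"], vL = params["v"], pL = params["p"];
  std::vector<mat> Q(nS), V(nS), P(nS);
  for (int s = 0; s < nS; ++s) {
    Q[s] = as<mat>(qL[s]); V[s] = as<mat>(vL[s]); P[s] = as<mat>(pL[s]);
  }
  mat BG = as<mat>(params["bg"]), BA = as<mat>(params["ba"]);
  mat JC = as<mat>(params["jc"]), AX = as<mat>(params["ax"]);

  const int perSensor = 9 * K + 6;
  const int C0 = nS * perSensor;
  const int nP = C0 + 72;
  auto stateCol = [&](int s, int k, int c) { return s * perSensor + k * 9 + c; };
  auto biasCol = [&](int s, int c) { return s * perSensor + 9 * K + c; };
  auto jcCol = [&](int j, int c) { return C0 + j * 3 + c; };
  auto axCol = [&](int j, int c) { return C0 + 36 + j * 3 + c; };

  bool hasPrior = problem.containsElementNamed("hipPrior") &&
    !Rf_isNull(problem["hipPrior"]);
  ivec priorIdx; mat priorMean; std::vector<mat> priorW;
  if (hasPrior) {
    List hp = problem["hipPrior"];
    priorIdx = as<ivec>(hp["idx"]);
    priorMean = as<mat>(hp["mean"]);
    List WL = hp["W"];
    for (int i = 0; i < 4; ++i) priorW.push_back(as<mat>(WL[i]));
  }

  const int nInert = nS * (K - 1) * 9;
  const int nJc = 6 * K * 3;
  int nHingeJoints = 0;
  for (int j = 0; j < 6; ++j) if (hingeUse(j)) ++nHingeJoints;
  const int nHinge = nHingeJoints * K * 3;
  const int nUnit = 12;
  const int nPrior = hasPrior ? 12 : 0;
  const int nGauge = 7;
  const int nBiasPr = nS * 6;
  const int nJcPr = 36;
  const int nAxPr = 36;
  const int nR = nInert + nJc + nHinge + nUnit + nPrior + nGauge + nBiasPr +
    nJcPr + nAxPr;

  vec r(nR, fill::zeros);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (wantJac) {
    ti.reserve(3500000); tj.reserve(3500000); tx.reserve(3500000);
  }
  const double h = 1e-6, inv2h = 1.0 / (2e-6);
  double base[9], rp[9], rm[9];

  // ---- inertial blocks -------------------------------------------------
  int row = 0;
  for (int s = 0; s < nS; ++s) {
    vec3 bg = BG.row(s).t(), ba = BA.row(s).t();
    for (int k = 0; k < K - 1; ++k) {
      uword i0 = (uword)k * m;
      Preint pre = preintegrate(gyro[s], accel[s], i0, m, dt, bg, ba);
      vec4 qk = Q[s].row(k).t(), qk1 = Q[s].row(k + 1).t();
      vec3 vk = V[s].row(k).t(), vk1 = V[s].row(k + 1).t();
      vec3 pk = P[s].row(k).t(), pk1 = P[s].row(k + 1).t();
      inertialRes(qk, vk, pk, qk1, vk1, pk1, pre, Dt, dt2S1, g,
                  sR, sv, sp, base);
      for (int i = 0; i < 9; ++i) r(row + i) = base[i];
      if (wantJac) {
        // state coordinates of keyframes k and k+1
        for (int which = 0; which < 2; ++which) {
          for (int c = 0; c < 9; ++c) {
            vec4 qa = qk, qb = qk1; vec3 va = vk, vb = vk1, pa = pk, pb = pk1;
            // plus
            applyStatePert(qa, va, pa, qb, vb, pb, which, c, h);
            inertialRes(qa, va, pa, qb, vb, pb, pre, Dt, dt2S1, g,
                        sR, sv, sp, rp);
            qa = qk; qb = qk1; va = vk; vb = vk1; pa = pk; pb = pk1;
            applyStatePert(qa, va, pa, qb, vb, pb, which, c, -h);
            inertialRes(qa, va, pa, qb, vb, pb, pre, Dt, dt2S1, g,
                        sR, sv, sp, rm);
            int col = stateCol(s, k + which, c);
            pushCol(ti, tj, tx, row, col, rp, rm, inv2h, 9);
          }
        }
        // bias coordinates: re-preintegrate
        for (int c = 0; c < 6; ++c) {
          vec3 bgp = bg, bap = ba, bgm = bg, bam = ba;
          if (c < 3) { bgp(c) += h; bgm(c) -= h; }
          else { bap(c - 3) += h; bam(c - 3) -= h; }
          Preint Pp = preintegrate(gyro[s], accel[s], i0, m, dt, bgp, bap);
          Preint Pm = preintegrate(gyro[s], accel[s], i0, m, dt, bgm, bam);
          inertialRes(qk, vk, pk, qk1, vk1, pk1, Pp, Dt, dt2S1, g,
                      sR, sv, sp, rp);
          inertialRes(qk, vk, pk, qk1, vk1, pk1, Pm, Dt, dt2S1, g,
                      sR, sv, sp, rm);
          pushCol(ti, tj, tx, row, biasCol(s, c), rp, rm, inv2h, 9);
        }
      }
      row += 9;
    }
  }

  // ---- joint-center blocks --------------------------------------------
  for (int j = 0; j < 6; ++j) {
    int sA = joints(j, 0) - 1, sB = joints(j, 1) - 1;
    int vA = joints(j, 2) - 1, vB = joints(j, 3) - 1;
    for (int k = 0; k < K; ++k) {
      vec4 qA = Q[sA].row(k).t(), qB = Q[sB].row(k).t();
      vec3 pA = P[sA].row(k).t(), pB = P[sB].row(k).t();
      vec3 sa = JC.row(vA).t(), sb = JC.row(vB).t();
      auto res = [&](const vec4& qa, const vec3& pa, const vec4& qb,
                     const vec3& pb, const vec3& va, const vec3& vb,
                     double* out) {
        vec3 rr = ((pa + qrot(qa, va)) - (pb + qrot(qb, vb))) / sigJc;
        out[0] = rr(0); out[1] = rr(1); out[2] = rr(2);
      };
      res(qA, pA, qB, pB, sa, sb, base);
      for (int i = 0; i < 3; ++i) r(row + i) = base[i];
      if (wantJac) {
        for (int c = 0; c < 18; ++c) {
          vec4 qa = qA, qb = qB; vec3 pa = pA, pb = pB, va = sa, vb = sb;
          applyJcPert(qa, pa, qb, pb, va, vb, c, h);
          res(qa, pa, qb, pb, va, vb, rp);
          qa = qA; qb = qB; pa = pA; pb = pB; va = sa; vb = sb;
          applyJcPert(qa, pa, qb, pb, va, vb, c, -h);
          res(qa, pa, qb, pb, va, vb, rm);
          int col;
          if (c < 3)       col = stateCol(sA, k, c);          // theta A
          else if (c < 6)  col = stateCol(sA, k, 6 + (c - 3)); // p A
          else if (c < 9)  col = stateCol(sB, k, c - 6);       // theta B
          else if (c < 12) col = stateCol(sB, k, 6 + (c - 9)); // p B
          else if (c < 15) col = jcCol(vA, c - 12);
          else             col = jcCol(vB, c - 15);
          pushCol(ti, tj, tx, row, col, rp, rm, inv2h, 3);
        }
      }
      row += 3;
    }
  }

  // ---- hinge blocks ----------------------------------------------------
  for (int j = 0; j < 6; ++j) {
    if (!hingeUse(j)) continue;
    int sA = joints(j, 0) - 1, sB = joints(j, 1) - 1;
    int aA = joints(j, 4) - 1, aB = joints(j, 5) - 1;
    double sh = sigHinge(j);
    for (int k = 0; k < K; ++k) {
      vec4 qA = Q[sA].row(k).t(), qB = Q[sB].row(k).t();
      vec3 aa = AX.row(aA).t(), ab = AX.row(aB).t();
      auto res = [&](const vec4& qa, const vec4& qb, const vec3& va,
                     const vec3& vb, double* out) {
        vec3 rr = (qrot(qa, va) - qrot(qb, vb)) / sh;
        out[0] = rr(0); out[1] = rr(1); out[2] = rr(2);
      };
      res(qA, qB, aa, ab, base);
      for (int i = 0; i < 3; ++i) r(row + i) = base[i];
      if (wantJac) {
        for (int c = 0; c < 12; ++c) {
          vec4 qa = qA, qb = qB; vec3 va = aa, vb = ab;
          applyHingePert(qa, qb, va, vb, c, h);
          res(qa, qb, va, vb, rp);
          qa = qA; qb = qB; va = aa; vb = ab;
          applyHingePert(qa, qb, va, vb, c, -h);
          res(qa, qb, va, vb, rm);
          int col;
          if (c < 3)       col = stateCol(sA, k, c);
          else if (c < 6)  col = stateCol(sB, k, c - 3);
          else if (c < 9)  col = axCol(aA, c - 6);
          else             col = axCol(aB, c - 9);
          pushCol(ti, tj, tx, row, col, rp, rm, inv2h, 3);
        }
      }
      row += 3;
    }
  }

  // ---- axis unit-norm --------------------------------------------------
  for (int j = 0; j < 12; ++j) {
    vec3 a = AX.row(j).t();
    r(row) = (dot(a, a) - 1.0) / sigUnit;
    if (wantJac) {
      for (int c = 0; c < 3; ++c) {
        ti.push_back(row + 1); tj.push_back(axCol(j, c) + 1);
        tx.push_back(2.0 * a(c) / sigUnit);
      }
    }
    row += 1;
  }

  // ---- hip-connected vector priors ------------------------------------
  if (hasPrior) {
    for (int i = 0; i < 4; ++i) {
      int v = priorIdx(i) - 1;
      vec3 d = JC.row(v).t() - priorMean.row(i).t();
      vec3 rr = priorW[i] * d;
      for (int c = 0; c < 3; ++c) r(row + c) = rr(c);
      if (wantJac)
        for (int cc = 0; cc < 3; ++cc)      // column of d
          for (int rr2 = 0; rr2 < 3; ++rr2) {
            double val = priorW[i](rr2, cc);
            if (val != 0) {
              ti.push_back(row + rr2 + 1);
              tj.push_back(jcCol(v, cc) + 1);
              tx.push_back(val);
            }
          }
      row += 3;
    }
  }

  // ---- gauge prior on the reference (lumbar) first keyframe ------------
  {
    int s = gaugeSensor;
    vec3 p1 = P[s].row(0).t(), v1 = V[s].row(0).t();
    vec4 q1 = Q[s].row(0).t();
    for (int c = 0; c < 3; ++c) {
      r(row + c) = p1(c) / sigGp;
      r(row + 3 + c) = v1(c) / sigGv;
      if (wantJac) {
        ti.push_back(row + c + 1); tj.push_back(stateCol(s, 0, 6 + c) + 1);
        tx.push_back(1.0 / sigGp);
        ti.push_back(row + 3 + c + 1); tj.push_back(stateCol(s, 0, 3 + c) + 1);
        tx.push_back(1.0 / sigGv);
      }
    }
    r(row + 6) = qyaw(q1) / sigGy;
    if (wantJac) {
      for (int c = 0; c < 3; ++c) {
        vec3 e = {0, 0, 0}; e(c) = h;
        double yp = qyaw(qmul(q1, qexpv(e)));
        e(c) = -h;
        double ym = qyaw(qmul(q1, qexpv(e)));
        double val = (yp - ym) * inv2h / sigGy;
        if (val != 0) {
          ti.push_back(row + 7); tj.push_back(stateCol(s, 0, c) + 1);
          tx.push_back(val);
        }
      }
    }
    row += 7;
  }

  // ---- bias priors ------------------------------------------------------
  for (int s = 0; s < nS; ++s) {
    for (int c = 0; c < 3; ++c) {
      r(row + c) = BG(s, c) / sigBg;
      r(row + 3 + c) = BA(s, c) / sigBa;
      if (wantJac) {
        ti.push_back(row + c + 1); tj.push_back(biasCol(s, c) + 1);
        tx.push_back(1.0 / sigBg);
        ti.push_back(row + 3 + c + 1); tj.push_back(biasCol(s, 3 + c) + 1);
        tx.push_back(1.0 / sigBa);
      }
    }
    row += 6;
  }

  // ---- weak trust prior on all joint-center vectors --------------------
  // centered on the initialization's estimate: bounds the along-axis null
  // direction of pure-hinge joints without shrinking identifiable
  // components toward zero
  mat jcCenter(12, 3, fill::zeros);
  if (problem.containsElementNamed("jcPriorCenter") &&
      !Rf_isNull(problem["jcPriorCenter"]))
    jcCenter = as<mat>(problem["jcPriorCenter"]);
  for (int j = 0; j < 12; ++j) {
    for (int c = 0; c < 3; ++c) {
      r(row + c) = (JC(j, c) - jcCenter(j, c)) / sigJcPrior;
      if (wantJac) {
        ti.push_back(row + c + 1); tj.push_back(jcCol(j, c) + 1);
        tx.push_back(1.0 / sigJcPrior);
      }
    }
    row += 3;
  }

  // ---- weak nominal prior on the hinge axes ----------------------------
  // sensors are strapped roughly aligned with their segment, so every
  // hinge axis lies within a few tens of degrees of the sensor x axis;
  // this blocks spurious minima in which a whole distal chain twists
  // about a hinge with the free axis estimate following it
  for (int j = 0; j < 12; ++j) {
    r(row) = (AX(j, 0) - 1.0) / sigAxPrior;
    r(row + 1) = AX(j, 1) / sigAxPrior;
    r(row + 2) = AX(j, 2) / sigAxPrior;
    if (wantJac) {
      for (int c = 0; c < 3; ++c) {
        ti.push_back(row + c + 1); tj.push_back(axCol(j, c) + 1);
        tx.push_back(1.0 / sigAxPrior);
      }
    }
    row += 3;
  }

  if (!wantJac) return List::create(_["r"] = r, _["nP"] = nP, _["nR"] = nR);
  return List::create(_["r"] = r, _["nP"] = nP, _["nR"] = nR,
                      _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}
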