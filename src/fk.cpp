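// Forward kinematics and analytic Jacobian over a compiled skeletal model.
//
// The model arrives pre-compiled from R as flat arrays in level order, so a
// parent's world transform is always available before its children.  Joint
// frames (Euler orientation matrices) are constant and precomputed on the R
// side; only the motion rotations and scaled translations are rebuilt per
// frame.  Angles are radians, translations metres; body scales are the ratio
// between subject and default segment dimensions (all-ones = default model).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat skew3(const vec& a) {
  mat S(3, 3, fill::zeros);
  S(0, 1) = -a(2); S(0, 2) =  a(1);
  S(1, 0) =  a(2); S(1, 2) = -a(0);
  S(2, 0) = -a(1); S(2, 1) =  a(0);
  return S;
}

// Rodrigues: rotation by th about unit axis a.
static mat axang3(const vec& a, double th) {
  mat S = skew3(a);
  return eye(3, 3) + std::sin(th) * S + (1.0 - std::cos(th)) * (S * S);
}

// Directional derivative of G(a, th) w.r.t. the axis, in direction da.
static mat dG_daxis(const vec& a, double th, const vec& da) {
  mat S = skew3(a), Sd = skew3(da);
  return std::sin(th) * Sd + (1.0 - std::cos(th)) * (Sd * S + S * Sd);
}

// Motion rotation R3*R2*R1 with later axes pre-rotated by the accumulated
// earlier rotations; optionally its partials w.r.t. each angle.
static void motion_rot(const mat& axes, const vec& th, int ndof,
                       mat& Rm, cube* dRm) {
  Rm = eye(3, 3);
  if (dRm) dRm->zeros();
  if (ndof == 0) return;

  vec a1 = axes.col(0);
  mat R1 = axang3(a1, th(0));
  if (ndof == 1) {
    Rm = R1;
    if (dRm) dRm->slice(0) = skew3(a1) * R1;
    return;
  }
  vec a2 = R1 * axes.col(1);
  mat R2 = axang3(a2, th(1));
  mat dR1_1 = skew3(a1) * R1;
  mat dR2_1, dR2_2;
  if (dRm || ndof == 3) {
    dR2_1 = dG_daxis(a2, th(1), skew3(a1) * a2);
    dR2_2 = skew3(a2) * R2;
  }
  if (ndof == 2) {
    Rm = R2 * R1;
    if (dRm) {
      dRm->slice(0) = dR2_1 * R1 + R2 * dR1_1;
      dRm->slice(1) = dR2_2 * R1;
    }
    return;
  }
  vec a3 = R2 * R1 * axes.col(2);
  mat R3 = axang3(a3, th(2));
  Rm = R3 * R2 * R1;
  if (dRm) {
    vec da3_1 = (dR2_1 * R1 + R2 * dR1_1) * axes.col(2);
    vec da3_2 = dR2_2 * R1 * axes.col(2);
    mat dR3_1 = dG_daxis(a3, th(2), da3_1);
    mat dR3_2 = dG_daxis(a3, th(2), da3_2);
    mat dR3_3 = skew3(a3) * R3;
    dRm->slice(0) = dR3_1 * R2 * R1 + R3 * dR2_1 * R1 + R3 * R2 * dR1_1;
    dRm->slice(1) = dR3_2 * R2 * R1 + R3 * dR2_2 * R1;
    dRm->slice(2) = dR3_3 * R2 * R1;
  }
}

struct CModel {
  int nb, nj, nm, nq;
  ivec jparent, jchild, ndof;
  mat Tp, Tc;
  cube Fp, Fc;       // constant joint-frame Euler matrices
  cube axes;         // 3 x 3 x nj (columns = dof axes, identity-padded)
  imat coordix;      // 3 x nj, 0-based indices into q, -1 pad
  int root_body, root_ndof;
  mat root_axes, root_Fc;
  ivec root_coordix;
  ivec mbody;
  mat moff;
  Rcpp::List mpath;  // per marker: integer vector of joint indices on path
};

static CModel unpack(const Rcpp::List& cm) {
  CModel M;
  M.nb = Rcpp::as<int>(cm["n_body"]);
  M.nj = Rcpp::as<int>(cm["n_joint"]);
  M.nm = Rcpp::as<int>(cm["n_marker"]);
  M.nq = Rcpp::as<int>(cm["n_coord"]);
  M.jparent = Rcpp::as<ivec>(cm["joint_parent"]);
  M.jchild = Rcpp::as<ivec>(cm["joint_child"]);
  M.ndof = Rcpp::as<ivec>(cm["joint_ndof"]);
  M.Tp = Rcpp::as<mat>(cm["Tp"]);
  M.Tc = Rcpp::as<mat>(cm["Tc"]);
  M.Fp = Rcpp::as<cube>(cm["Fp"]);
  M.Fc = Rcpp::as<cube>(cm["Fc"]);
  M.axes = Rcpp::as<cube>(cm["axes"]);
  M.coordix = Rcpp::as<imat>(cm["coordix"]);
  M.root_body = Rcpp::as<int>(cm["root_body"]);
  M.root_ndof = Rcpp::as<int>(cm["root_ndof"]);
  M.root_axes = Rcpp::as<mat>(cm["root_axes"]);
  M.root_Fc = Rcpp::as<mat>(cm["root_Fc"]);
  M.root_coordix = Rcpp::as<ivec>(cm["root_coordix"]);
  M.mbody = Rcpp::as<ivec>(cm["marker_body"]);
  M.moff = Rcpp::as<mat>(cm["marker_offset"]);
  M.mpath = Rcpp::as<Rcpp::List>(cm["marker_path"]);
  return M;
}

// Core FK shared by the exported entry points.  Fills per-body world
// transforms, joint (child-origin) and marker positions; optionally caches
// the per-joint quantities the Jacobian needs.
struct FKCache {
  cube W;                      // 4 x 4 x nb
  mat joint_pos, marker_pos;   // 3 x nj, 3 x nm
  std::vector<mat> Wp;         // parent world transform per joint
  std::vector<mat> Rm;         // motion rotation per joint
  mat root_Rm;                 // root joint motion rotation
};

static void fk_core(const CModel& M, const mat& beta, const vec& q,
                    const mat& root_in, bool root_given, FKCache& C,
                    bool keep) {
  C.W.set_size(4, 4, M.nb);
  C.joint_pos.set_size(3, M.nj);
  C.marker_pos.set_size(3, M.nm);
  if (keep) { C.Wp.resize(M.nj); C.Rm.resize(M.nj); }

  mat Wroot(4, 4, fill::eye);
  if (root_given) {
    Wroot = root_in;
  } else if (M.root_ndof > 0) {
    vec th(3, fill::zeros);
    for (int i = 0; i < M.root_ndof; ++i) th(i) = q(M.root_coordix(i));
    mat Rm;
    motion_rot(M.root_axes, th, M.root_ndof, Rm, nullptr);
    Wroot.submat(0, 0, 2, 2) = Rm * M.root_Fc.t();
    if (keep) C.root_Rm = Rm;
  }
  C.W.slice(M.root_body) = Wroot;

  for (int k = 0; k < M.nj; ++k) {
    int pb = M.jparent(k), cb = M.jchild(k);
    vec Tph = M.Tp.col(k) % beta.col(pb);
    vec Tch = M.Tc.col(k) % beta.col(cb);
    vec th(3, fill::zeros);
    for (int i = 0; i < M.ndof(k); ++i) th(i) = q(M.coordix(i, k));
    mat Rm;
    motion_rot(M.axes.slice(k), th, M.ndof(k), Rm, nullptr);
    mat R = M.Fp.slice(k) * Rm * M.Fc.slice(k).t();
    vec t = Tph - R * Tch;
    mat L(4, 4, fill::eye);
    L.submat(0, 0, 2, 2) = R;
    L.submat(0, 3, 2, 3) = t;
    const mat& Wp = C.W.slice(pb);
    C.W.slice(cb) = Wp * L;
    C.joint_pos.col(k) = C.W.slice(cb).submat(0, 3, 2, 3);
    if (keep) { C.Wp[k] = Wp; C.Rm[k] = Rm; }
  }

  for (int m = 0; m < M.nm; ++m) {
    int b = M.mbody(m);
    const mat& Wb = C.W.slice(b);
    vec d = M.moff.col(m) % beta.col(b);
    C.marker_pos.col(m) =
      Wb.submat(0, 0, 2, 2) * d + Wb.submat(0, 3, 2, 3);
  }
}

// [[Rcpp::export]]
Rcpp::List fk_pose_cpp(const Rcpp::List& cm, const arma::mat& beta,
                       const arma::vec& q, const arma::mat& root) {
  CModel M = unpack(cm);
  FKCache C;
  bool root_given = root.n_rows == 4;
  fk_core(M, beta, q, root, root_given, C, false);
  return Rcpp::List::create(
    Rcpp::Named("world") = C.W,
    Rcpp::Named("joint_pos") = C.joint_pos,
    Rcpp::Named("marker_pos") = C.marker_pos);
}

// Batched FK over frames: Q is nq x F; roots either 3 x 3 x F or empty.
// [[Rcpp::export]]
Rcpp::List fk_sequence_cpp(const Rcpp::List& cm, const arma::mat& beta,
                           const arma::mat& Q, const arma::cube& roots) {
  CModel M = unpack(cm);
  int F = Q.n_cols;
  bool have_roots = roots.n_slices == (unsigned)F && roots.n_rows == 3;
  cube markers(3, M.nm, F), joints(3, M.nj, F);
  FKCache C;
  mat root4(4, 4, fill::eye);
  for (int f = 0; f < F; ++f) {
    bool rg = false;
    if (have_roots) {
      root4.submat(0, 0, 2, 2) = roots.slice(f);
      rg = true;
    }
    fk_core(M, beta, Q.col(f), root4, rg, C, false);
    markers.slice(f) = C.marker_pos;
    joints.slice(f) = C.joint_pos;
  }
  return Rcpp::List::create(
    Rcpp::Named("marker_pos") = markers,
    Rcpp::Named("joint_pos") = joints);
}

static mat rigid_inverse(const mat& W) {
  mat inv(4, 4, fill::eye);
  mat Rt = W.submat(0, 0, 2, 2).t();
  inv.submat(0, 0, 2, 2) = Rt;
  inv.submat(0, 3, 2, 3) = -Rt * W.submat(0, 3, 2, 3);
  return inv;
}

// Analytic Jacobian of all marker coordinates w.r.t. q (and optionally the
// per-body scale ratios).  Rows are (x,y,z) per marker, stacked by marker.
// [[Rcpp::export]]
Rcpp::List fk_jacobian_cpp(const Rcpp::List& cm, const arma::mat& beta,
                           const arma::vec& q, const arma::mat& root,
                           bool want_beta) {
  CModel M = unpack(cm);
  FKCache C;
  bool root_given = root.n_rows == 4;
  fk_core(M, beta, q, root, root_given, C, true);

  mat Jq(3 * M.nm, M.nq, fill::zeros);
  mat Jb;
  if (want_beta) Jb.zeros(3 * M.nm, 3 * M.nb);

  std::vector<mat> invW(M.nb);
  for (int b = 0; b < M.nb; ++b) invW[b] = rigid_inverse(C.W.slice(b));

  // Per-joint derivative blocks, computed once then applied along each
  // marker's root-to-anchor path.
  std::vector<cube> Dk(M.nj);       // 4x4x ndof angle-derivative transforms
  std::vector<mat> Ak(M.nj), Bk(M.nj);
  for (int k = 0; k < M.nj; ++k) {
    int pb = M.jparent(k), cb = M.jchild(k);
    vec Tch = M.Tc.col(k) % beta.col(cb);
    vec th(3, fill::zeros);
    for (int i = 0; i < M.ndof(k); ++i) th(i) = q(M.coordix(i, k));
    mat Rm;
    cube dRm(3, 3, 3);
    motion_rot(M.axes.slice(k), th, M.ndof(k), Rm, &dRm);
    const mat& Fp = M.Fp.slice(k);
    const mat& Fc = M.Fc.slice(k);
    Dk[k].zeros(4, 4, std::max(1, (int)M.ndof(k)));
    for (int i = 0; i < M.ndof(k); ++i) {
      mat dR = Fp * dRm.slice(i) * Fc.t();
      mat D(4, 4, fill::zeros);
      D.submat(0, 0, 2, 2) = dR;
      D.submat(0, 3, 2, 3) = -dR * Tch;
      Dk[k].slice(i) = C.Wp[k] * D;
    }
    if (want_beta) {
      Ak[k] = C.Wp[k].submat(0, 0, 2, 2) * Fp;        // parent-translation dir
      Bk[k] = Ak[k] * Rm;                             // child-translation dir
    }
  }

  // Root-angle derivatives touch every marker.
  cube Droot;
  if (!root_given && M.root_ndof > 0) {
    vec th(3, fill::zeros);
    for (int i = 0; i < M.root_ndof; ++i) th(i) = q(M.root_coordix(i));
    mat Rm;
    cube dRm(3, 3, 3);
    motion_rot(M.root_axes, th, M.root_ndof, Rm, &dRm);
    Droot.zeros(4, 4, M.root_ndof);
    for (int i = 0; i < M.root_ndof; ++i)
      Droot.slice(i).submat(0, 0, 2, 2) = dRm.slice(i) * M.root_Fc.t();
  }

  for (int m = 0; m < M.nm; ++m) {
    int r0 = 3 * m;
    vec ph(4, fill::ones);
    ph.subvec(0, 2) = C.marker_pos.col(m);
    Rcpp::IntegerVector path = M.mpath[m];
    for (int pi = 0; pi < path.size(); ++pi) {
      int k = path[pi];
      int pb = M.jparent(k), cb = M.jchild(k);
      vec v = invW[cb] * ph;
      for (int i = 0; i < M.ndof(k); ++i) {
        vec dp = Dk[k].slice(i).submat(0, 0, 2, 3) * v;
        Jq.submat(r0, M.coordix(i, k), r0 + 2, M.coordix(i, k)) = dp;
      }
      if (want_beta) {
        for (int i = 0; i < 3; ++i) {
          Jb.submat(r0, 3 * pb + i, r0 + 2, 3 * pb + i) +=
            Ak[k].col(i) * M.Tp(i, k);
          Jb.submat(r0, 3 * cb + i, r0 + 2, 3 * cb + i) +=
            -M.Tc(i, k) * Bk[k] * M.Fc.slice(k).row(i).t();
        }
      }
    }
    if (Droot.n_slices > 0) {
      vec v = invW[M.root_body] * ph;
      for (int i = 0; i < M.root_ndof; ++i) {
        vec dp = Droot.slice(i).submat(0, 0, 2, 3) * v;
        Jq.submat(r0, M.root_coordix(i), r0 + 2, M.root_coordix(i)) = dp;
      }
    }
    if (want_beta) {
      int b = M.mbody(m);
      const mat& Wb = C.W.slice(b);
      for (int i = 0; i < 3; ++i)
        Jb.submat(r0, 3 * b + i, r0 + 2, 3 * b + i) +=
          Wb.submat(0, 0, 2, 2).col(i) * M.moff(i, m);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("marker_pos") = C.marker_pos,
    Rcpp::Named("Jq") = Jq,
    Rcpp::Named("Jbeta") = Jb);
}
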