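// Batched forward rollout and backpropagation-through-time for the leaky
// low-rank pursuit RNN:
//   h_t = (1-alpha) h_{t-1} + alpha ( M Q^T tanh(h_{t-1}) / N + B u_t + b )
//   z_t = W_out tanh(h_t),  v_t = vmax z_t / (1 + ||z_t||)
//   p_{t+1} = resolve_boundary(p_t + v_t dt)
// Boundary resolution is treated as identity in the backward pass
// (straight-through).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline void resolve_boundary_inplace(mat& p, double L, bool periodic) {
  if (periodic) {
    p -= L * floor(p / L);
  } else {
    p = clamp(p, 0.0, L);
  }
}

// minimal-image displacement (periodic) or plain difference
static inline mat disp(const mat& a, const mat& b, double L, bool periodic) {
  mat d = a - b;
  if (periodic) d -= L * round(d / L);
  return d;
}

// [[Rcpp::export(name = ".bptt_core")]]
Rcpp::List bptt_core(const arma::mat& M, const arma::mat& Q,
                     const arma::mat& B, const arma::vec& b,
                     const arma::mat& Wout, const arma::cube& U,
                     const arma::mat& P0, const arma::cube& TG,
                     double alpha, double dt, double vmax, double L,
                     bool periodic, int loss_kind, bool squared,
                     bool want_grads, bool want_states) {
  const uword N = M.n_rows, r = M.n_cols, n_in = B.n_cols;
  const uword Bn = U.n_cols, T = U.n_slices;

  cube A, S, Z, V, P;
  if (want_states) {
    S.set_size(N, Bn, T);
    Z.set_size(2, Bn, T);
    V.set_size(2, Bn, T);
  }
  A.set_size(N, Bn, T);   // needed for the backward pass
  P.set_size(2, Bn, T);
  cube Zall(2, Bn, T);

  mat h(N, Bn, fill::zeros), a(N, Bn, fill::zeros);
  mat p = P0;
  for (uword t = 0; t < T; ++t) {
    mat rec = M * (Q.t() * a) / double(N);
    h = (1.0 - alpha) * h + alpha * (rec + B * U.slice(t) + repmat(b, 1, Bn));
    if (!h.is_finite())
      Rcpp::stop("non-finite hidden state at step %d", int(t) + 1);
    a = tanh(h);
    mat z = Wout * a;
    rowvec n = sqrt(sum(square(z), 0));
    mat v = z.each_row() % (vmax / (1.0 + n));
    A.slice(t) = a;
    Zall.slice(t) = z;
    P.slice(t) = p;
    if (want_states) { S.slice(t) = h; Z.slice(t) = z; V.slice(t) = v; }
    if (t + 1 < T) {
      p += v * dt;
      resolve_boundary_inplace(p, L, periodic);
    }
  }

  // per-position loss gradients
  mat D_T = disp(P.slice(T - 1), TG.slice(T - 1), L, periodic);
  rowvec nd_T = sqrt(sum(square(D_T), 0));
  vec end_distance = nd_T.t();
  double loss = 0.0;
  cube GP(2, Bn, T, fill::zeros);
  if (loss_kind == 0) {          // final distance
    loss = squared ? mean(square(nd_T)) : mean(nd_T);
    if (want_grads) {
      if (squared) GP.slice(T - 1) = 2.0 * D_T;
      else {
        rowvec sc = 1.0 / clamp(nd_T, 1e-12, datum::inf);
        sc.elem(find(nd_T <= 1e-12)).zeros();
        GP.slice(T - 1) = D_T.each_row() % sc;
      }
    }
  } else {                        // mean distance over steps
    for (uword t = 0; t < T; ++t) {
      mat Dt = disp(P.slice(t), TG.slice(t), L, periodic);
      rowvec nd = sqrt(sum(square(Dt), 0));
      loss += (squared ? mean(square(nd)) : mean(nd)) / double(T);
      if (want_grads) {
        if (squared) GP.slice(t) = 2.0 * Dt / double(T);
        else {
          rowvec sc = 1.0 / clamp(nd * double(T), 1e-12, datum::inf);
          sc.elem(find(nd <= 1e-12)).zeros();
          GP.slice(t) = Dt.each_row() % sc;
        }
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("end_distance") = end_distance);
  if (want_states) {
    out["A"] = A; out["S"] = S; out["Z"] = Z; out["V"] = V; out["P"] = P;
  }
  if (!want_grads) return out;

  // g_v_t = dt * sum_{tau > t} dL/dp_tau
  cube GV(2, Bn, T, fill::zeros);
  mat acc(2, Bn, fill::zeros);
  for (uword t = T; t-- > 0;) {
    GV.slice(t) = dt * acc;
    acc += GP.slice(t);
  }

  mat gM(N, r, fill::zeros), gQ(N, r, fill::zeros);
  mat gB(N, n_in, fill::zeros), gWout(2, N, fill::zeros);
  vec gb(N, fill::zeros);
  mat delta_next(N, Bn, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat& a_t = A.slice(t);
    const mat& z = Zall.slice(t);
    rowvec n = sqrt(sum(square(z), 0));
    const mat& gv = GV.slice(t);
    rowvec dots = sum(z % gv, 0);
    rowvec coef(Bn, fill::zeros);
    uvec big = find(n > 1e-12);
    coef.elem(big) = dots.elem(big) / (n.elem(big) % square(1.0 + n.elem(big)));
    mat gz = vmax * (gv.each_row() % (1.0 / (1.0 + n)) - z.each_row() % coef);

    mat ga = Wout.t() * gz + alpha * (Q * (M.t() * delta_next) / double(N));
    mat delta = ga % (1.0 - square(a_t)) + (1.0 - alpha) * delta_next;
    gWout += gz * a_t.t();
    gB += alpha * (delta * U.slice(t).t());
    gb += alpha * sum(delta, 1);
    if (t > 0) {
      const mat& a_prev = A.slice(t - 1);
      gM += (alpha / double(N)) * (delta * (a_prev.t() * Q));
      gQ += (alpha / double(N)) * (a_prev * (delta.t() * M));
    }
    delta_next = delta;
  }
  double Bd = double(Bn);
  out["grads"] = Rcpp::List::create(
      Rcpp::Named("M") = gM / Bd, Rcpp::Named("Q") = gQ / Bd,
      Rcpp::Named("B") = gB / Bd, Rcpp::Named("b") = gb / Bd,
      Rcpp::Named("W_out") = gWout / Bd);
  return out;
}
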