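// Per-variant additive-dosage logistic regression (Wald), with a Firth
// bias-reduced refit on separation or non-convergence. The design matrix is
// [covariates | dosage]; only the dosage coefficient is reported.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double loglik(const vec& y, const vec& mu) {
    return accu(y % log(mu) + (1.0 - y) % log(1.0 - mu));
}

static void linkinv(const vec& eta, vec& mu) {
    mu = 1.0 / (1.0 + exp(-clamp(eta, -30.0, 30.0)));
}

// standard IRLS; returns true on convergence, fills beta/XtWX_inv/mu
static bool irls_fit(const mat& X, const vec& y, vec& beta, mat& cov,
                     vec& mu, double tol, int maxit) {
    const uword p = X.n_cols;
    beta.zeros(p);
    vec eta(X.n_rows), w, z;
    for (int it = 0; it < maxit; ++it) {
        eta = X * beta;
        linkinv(eta, mu);
        w = mu % (1.0 - mu);
        w = clamp(w, 1e-10, 0.25);
        mat XtWX = X.t() * (X.each_col() % w);
        vec score = X.t() * (y - mu);
        vec delta;
        if (!solve(delta, XtWX, score, solve_opts::likely_sympd))
            return false;
        beta += delta;
        if (abs(delta).max() < tol) {
            eta = X * beta;
            linkinv(eta, mu);
            w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
            mat XtWXf = X.t() * (X.each_col() % w);
            if (!inv_sympd(cov, XtWXf)) return false;
            return true;
        }
    }
    return false;
}

// Firth penalized logistic with step-halving
static bool firth_fit(const mat& X, const vec& y, vec& beta, mat& cov,
                      double tol, int maxit) {
    const uword p = X.n_cols;
    beta.zeros(p);
    vec eta, mu, w;
    double ll_old = -datum::inf;
    for (int it = 0; it < maxit; ++it) {
        eta = X * beta;
        linkinv(eta, mu);
        w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
        mat XtWX = X.t() * (X.each_col() % w);
        mat XtWX_inv;
        if (!inv_sympd(XtWX_inv, XtWX)) return false;
        // hat diagonal h_i = w_i * x_i' (X'WX)^-1 x_i
        vec h(X.n_rows);
        mat XA = X * XtWX_inv;      // n x p
        h = w % sum(XA % X, 1);
        vec score = X.t() * (y - mu + h % (0.5 - mu));
        vec delta = XtWX_inv * score;
        // step halving on the penalized log-likelihood
        double val, sign;
        log_det(val, sign, XtWX);
        double ll_pen = loglik(y, mu) + 0.5 * val;
        double step = 1.0;
        vec beta_new;
        for (int half = 0; half < 12; ++half) {
            beta_new = beta + step * delta;
            vec eta2 = X * beta_new, mu2;
            linkinv(eta2, mu2);
            vec w2 = clamp(mu2 % (1.0 - mu2), 1e-10, 0.25);
            mat XtWX2 = X.t() * (X.each_col() % w2);
            double v2, s2;
            log_det(v2, s2, XtWX2);
            double ll2 = loglik(y, mu2) + 0.5 * v2;
            if (std::isfinite(ll2) && (ll2 >= ll_pen - 1e-10 || step < 1e-3))
                break;
            step *= 0.5;
        }
        vec change = beta_new - beta;
        beta = beta_new;
        if (abs(change).max() < tol) {
            eta = X * beta;
            linkinv(eta, mu);
            w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
            mat XtWXf = X.t() * (X.each_col() % w);
            if (!inv_sympd(cov, XtWXf)) return false;
            return true;
        }
        ll_old = ll_pen;
    }
    // report the last iterate with its covariance rather than failing hard
    eta = X * beta;
    linkinv(eta, mu);
    w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    mat XtWXf = X.t() * (X.each_col() % w);
    return inv_sympd(cov, XtWXf);
}

// C: n x pc covariates (including intercept), G: n x m dosages (complete),
// y: n binary. Returns m x 4: beta_g, se_g, code (0 wald, 1 firth, 2 fail),
// converged flag.
// [[Rcpp::export]]
arma::mat cpp_logistic_scan(const arma::mat& C, const arma::mat& G,
                            const arma::vec& y, double tol, int maxit,
                            int firth_maxit) {
    const uword n = C.n_rows, m = G.n_cols, pc = C.n_cols;
    mat out(m, 4);
    out.fill(datum::nan);
    mat X(n, pc + 1);
    X.cols(0, pc - 1) = C;
    for (uword j = 0; j < m; ++j) {
        X.col(pc) = G.col(j);
        vec beta; mat cov; vec mu;
        bool ok = irls_fit(X, y, beta, cov, mu, tol, maxit);
        bool sep = ok && (mu.min() < 1e-8 || mu.max() > 1.0 - 1e-8);
        double code = 0;
        if (!ok || sep) {
            code = 1;
            ok = firth_fit(X, y, beta, cov, tol, firth_maxit);
        }
        if (!ok) {
            out(j, 2) = 2;
            continue;
        }
        out(j, 0) = beta(pc);
        out(j, 1) = std::sqrt(cov(pc, pc));
        out(j, 2) = code;
        out(j, 3) = 1;
    }
    return out;
}
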