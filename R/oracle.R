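#' Exhaustive quadrature oracle for the mixture posterior
#'
#' Independent verification of [sample_posterior()] on small datasets:
#' posterior expectations computed by deterministic numerical integration
#' over (rbar, d, s1, s2) with the d = 0 spike handled as a separate branch.
#' The sum over all 2^n clone assignments is carried out exactly: with a
#' fixed 0.5 mixing probability the assignments are independent given the
#' parameters, so the summed likelihood is the product over clones of the
#' two-component mixture pmf.  Trapezoidal quadrature; rbar and d share a
#' common logit-scale grid so the allele logits r1 = rbar - d/2 and
#' r2 = rbar + d/2 land on precomputed nodes.
#'
#' @param data data.frame with columns `m`, `N`; at most 12 clones (the
#'   oracle is O(grid^4) and meant for toy data).
#' @param prior a [mixture_prior()].
#' @param rbar_max half-width of the rbar grid.
#' @param h grid spacing on the logit scale (d spacing is 2h).
#' @param d_max upper integration limit for d.
#' @param n_s number of (log-spaced) quadrature nodes for each s.
#' @param s_range range of the s grids.
#' @return list with `rbar_mean`, `d_mean`, `allele1_percent`,
#'   `allele2_percent`, `p_d_gt_0`, `assign_p1`.
#' @export
grid_oracle_posterior <- function(data, prior = mixture_prior(),
                                  rbar_max = 8, h = 0.16, d_max = 12.8,
                                  n_s = 33, s_range = c(0.1, 400)) {
  stopifnot(all(c("m", "N") %in% names(data)))
  m <- data$m; N <- data$N
  n <- length(m)
  if (n > 12) stop("oracle infeasible for more than 12 clones")
  if (n < 1) stop("need at least one clone")

  n_half <- round(d_max / 2 / h)
  d_grid <- (0:n_half) * 2 * h
  n_r <- round(2 * rbar_max / h)
  rbar_grid <- -rbar_max + h * (0:n_r)
  n_rbar <- length(rbar_grid)
  r_ext <- -rbar_max - n_half * h + h * (0:(n_r + 2 * n_half))
  offset <- n_half  # rbar index i maps to ext index i + offset

  s_grid <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = n_s))

  trap_w <- function(x) {
    dx <- diff(x)
    c(dx[1] / 2, (dx[-length(dx)] + dx[-1]) / 2, dx[length(dx)] / 2)
  }

  # per-clone pmf over the (r, s) node grid, rescaled per clone for stability
  pmf_grid <- vector("list", n)
  mu_ext <- stats::plogis(r_ext)
  for (j in seq_len(n)) {
    A <- outer(mu_ext, s_grid, function(mu, s)
      exp(betabin_logpmf(m[j], N[j], s * mu, s * (1 - mu))))
    pmf_grid[[j]] <- A / max(A)
  }

  ws <- trap_w(s_grid) *
    stats::dgamma(s_grid, shape = prior$s_shape, rate = prior$s_rate)
  Ws <- outer(ws, ws)
  wr <- trap_w(rbar_grid) *
    stats::dnorm(rbar_grid, prior$rbar_mean, prior$rbar_sd)
  wd <- trap_w(d_grid) *
    stats::dgamma(d_grid, shape = prior$d_shape, rate = prior$d_rate) *
    (1 - prior$zero_mass)

  # c[i, k]: s-integrated likelihood at (rbar_i, d_k); assignment posterior
  # numerators accumulated alongside.
  acc <- list(Z = 0, rbar = 0, d = 0, mu1 = 0, mu2 = 0,
              assign = numeric(n), spike_Z = 0, spike_rbar = 0,
              spike_mu = 0, spike_assign = numeric(n))
  for (k in seq_along(d_grid)) {
    dk <- d_grid[k]
    k_off <- k - 1L
    for (i in seq_len(n_rbar)) {
      i1 <- i + offset - k_off
      i2 <- i + offset + k_off
      Ms <- vector("list", n)
      P <- matrix(1, n_s, n_s)
      for (j in seq_len(n)) {
        Mj <- 0.5 * matrix(pmf_grid[[j]][i1, ], n_s, n_s) +
              0.5 * matrix(pmf_grid[[j]][i2, ], n_s, n_s, byrow = TRUE)
        Ms[[j]] <- Mj
        P <- P * Mj
      }
      PW <- P * Ws
      cik <- sum(PW)
      if (cik == 0) next
      anum <- vapply(seq_len(n), function(j)
        sum(PW * (0.5 * matrix(pmf_grid[[j]][i1, ], n_s, n_s)) / Ms[[j]]),
        numeric(1))
      w_slab <- wr[i] * wd[k]
      acc$Z <- acc$Z + w_slab * cik
      acc$rbar <- acc$rbar + w_slab * cik * rbar_grid[i]
      acc$d <- acc$d + w_slab * cik * dk
      acc$mu1 <- acc$mu1 + w_slab * cik * mu_ext[i1]
      acc$mu2 <- acc$mu2 + w_slab * cik * mu_ext[i2]
      acc$assign <- acc$assign + w_slab * anum
      if (k == 1) {  # spike branch: d fixed at 0, point mass zero_mass
        w_sp <- wr[i] * prior$zero_mass
        acc$spike_Z <- acc$spike_Z + w_sp * cik
        acc$spike_rbar <- acc$spike_rbar + w_sp * cik * rbar_grid[i]
        acc$spike_mu <- acc$spike_mu + w_sp * cik * mu_ext[i1]
        acc$spike_assign <- acc$spike_assign + w_sp * anum
      }
    }
  }

  Z <- acc$Z + acc$spike_Z
  if (Z <= 0) stop("oracle underflow: zero evidence on the grid")
  list(rbar_mean = (acc$rbar + acc$spike_rbar) / Z,
       d_mean = acc$d / Z,
       allele1_percent = 100 * (acc$mu1 + acc$spike_mu) / Z,
       allele2_percent = 100 * (acc$mu2 + acc$spike_mu) / Z,
       p_d_gt_0 = acc$Z / Z,
       assign_p1 = (acc$assign + acc$spike_assign) / Z)
}
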