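# Independent oracles used across tests.

# Closed-form bias trajectory for a noiseless conflict block in the repeating
# quartet VP, V, VP, P. Returns, per trial, the accumulated total bias u
# (y only), the offset, and the y endpoint-offsets the observer should
# produce, from the scalar recursion u <- u + eta * (delta - u) applied on VP
# trials only.
oracle_conflict_traj <- function(w, eta, n_quartets = 21, step = 70 / 42) {
  types <- rep(c("VP", "V", "VP", "P"), n_quartets)
  n <- length(types)
  u <- 0
  n_vp <- 0
  out <- data.frame(type = types, offset = NA_real_, u = NA_real_,
                    endpoint_rel = NA_real_)
  for (i in seq_len(n)) {
    if (types[i] == "VP") {
      n_vp <- n_vp + 1
      delta <- n_vp * step
      # endpoint generated BEFORE the update uses the pre-update bias
      pre_u <- u
      out$endpoint_rel[i] <- w * (delta - (1 - w) * pre_u) +
        (1 - w) * (w * pre_u)
      u <- u + eta * (delta - u)
      out$offset[i] <- delta
    } else if (types[i] == "V") {
      delta <- n_vp * step
      out$offset[i] <- delta
      out$endpoint_rel[i] <- delta - (1 - w) * u
    } else {
      out$offset[i] <- n_vp * step
      out$endpoint_rel[i] <- w * u
    }
    out$u[i] <- u
  }
  out
}

# Textbook sums-of-squares decomposition for a fully within-participant
# 2 x 2 design. Returns F for the two main effects and the interaction.
oracle_rm_anova_2x2 <- function(values) {
  ids <- sort(unique(values$participant))
  la <- sort(unique(as.character(values$a)))
  lb <- sort(unique(as.character(values$b)))
  n <- length(ids)
  y <- array(NA_real_, c(n, 2, 2))
  for (i in seq_len(n)) for (j in 1:2) for (k in 1:2) {
    y[i, j, k] <- values$value[values$participant == ids[i] &
                                 values$a == la[j] & values$b == lb[k]]
  }
  grand <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- 2 * n * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a - grand, m_b - grand, "+") - grand)^2)
  ss_sa <- 2 * sum((m_sa - outer(m_s - grand, m_a - grand, "+") - grand)^2)
  ss_sb <- 2 * sum((m_sb - outer(m_s - grand, m_b - grand, "+") - grand)^2)
  resid <- y
  for (i in seq_len(n)) for (j in 1:2) for (k in 1:2) {
    resid[i, j, k] <- y[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
      m_s[i] + m_a[j] + m_b[k] - grand
  }
  ss_sab <- sum(resid^2)
  list(
    a = (ss_a / 1) / (ss_sa / (n - 1)),
    b = (ss_b / 1) / (ss_sb / (n - 1)),
    a_x_b = (ss_ab / 1) / (ss_sab / (n - 1)))
}

# Noiseless observer shortcut: parameters with all sigmas zero.
noiseless_params <- function(w_v, eta, b_p0 = c(0, 0), b_v0 = c(0, 0)) {
  observer_params(sigma_p = 0, sigma_v = 0, sigma_m = 0, w_v = w_v,
                  eta = eta, b_p0 = b_p0, b_v0 = b_v0)
}

# Quick synthetic table for the mixed-model tests: two sessions per
# participant with known fixed effects and iid noise.
make_sai_table <- function(n, betas = c(intercept = 100, ver_p = 0,
                                        conf_p = 1.8, ver_v = 0, conf_v = 0),
                           noise_sd = 10, ranef_sd = 0, seed = 1) {
  set.seed(seed)
  tab <- expand.grid(participant = seq_len(n),
                     session = c("conflict", "veridical"),
                     stringsAsFactors = FALSE)
  tab$recal_p <- rnorm(nrow(tab), 12, 6)
  tab$recal_v <- rnorm(nrow(tab), 30, 8)
  u <- rnorm(n, 0, ranef_sd)
  conf <- as.numeric(tab$session == "conflict")
  tab$delta_sai <- betas["intercept"] +
    (1 - conf) * betas["ver_p"] * tab$recal_p +
    conf * betas["conf_p"] * tab$recal_p +
    (1 - conf) * betas["ver_v"] * tab$recal_v +
    conf * betas["conf_v"] * tab$recal_v +
    u[tab$participant] + rnorm(nrow(tab), 0, noise_sd)
  tab
}
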