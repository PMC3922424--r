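# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately literal (nested loops, hand-rolled formulas) so they stay
# independent of the implementation paths they check.

small_atlas <- function(n_left = 2, n_right = 2, grid = c(8, 8, 4)) {
  atlas <- make_symmetric_atlas(grid, voxel_mm = 3, spacing_mm = 6)
  attach_hubs(atlas, synthetic_hub_table(atlas, n_left, n_right),
              quiet = TRUE)
}

atlas20 <- function() {
  make_symmetric_atlas(c(24, 24, 16), voxel_mm = 3, spacing_mm = 6,
                       hub_table = hub_table_synthetic20())
}

tiny_run <- function(data, tr = 2, motion = NULL, nuisance = NULL,
                     subject_id = "s1") {
  nt <- dim(data)[4]
  if (is.null(motion)) motion <- matrix(0, nt, 6)
  bold_run(data, tr_seconds = tr, voxel_mm = 3, motion_params = motion,
           subject_id = subject_id, nuisance = nuisance)
}

random_run <- function(dims = c(8, 8, 4), nt = 20, seed = 1, baseline = 100) {
  set.seed(seed)
  tiny_run(array(rnorm(prod(dims) * nt, mean = baseline), c(dims, nt)))
}

# --- oracles -------------------------------------------------------------

fd_oracle <- function(mp, radius = 50) {
  nt <- nrow(mp)
  fd <- numeric(nt)
  for (t in 2:nt) {
    s <- 0
    for (j in 1:6) {
      d <- abs(mp[t, j] - mp[t - 1, j])
      if (j > 3) d <- d * radius
      s <- s + d
    }
    fd[t] <- s
  }
  fd
}

dvars_oracle <- function(m, ref) {
  nt <- ncol(m)
  out <- numeric(nt)
  for (t in 2:nt) {
    acc <- 0
    for (v in seq_len(nrow(m))) acc <- acc + (m[v, t] - m[v, t - 1])^2
    out[t] <- sqrt(acc / nrow(m)) / ref * 100
  }
  out
}

roi_mean_oracle <- function(data4d, labels) {
  nt <- dim(data4d)[4]
  n <- max(labels)
  out <- matrix(NA_real_, n, nt)
  for (r in seq_len(n)) {
    idx <- which(labels == r)
    for (t in seq_len(nt)) {
      vol <- data4d[, , , t]
      out[r, t] <- mean(vol[idx])
    }
  }
  out
}

fisher_oracle <- function(values) {
  n <- nrow(values)
  z <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      r <- cor(values[a, ], values[b, ])
      r <- max(min(r, 1 - 1e-12), -(1 - 1e-12))
      z[a, b] <- atanh(r)
    }
  }
  z
}

# Literal BH step-up: largest k with p_(k) <= k/m * q, reject all p <= p_(k).
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[p <= ps[k]] <- TRUE
  rej
}

# Simulated lateralization tables (per-subject li draws) for stats-level
# Monte-Carlo tests that do not need the imaging stages.
li_table_sim <- function(connections, n_control, n_autism, li_sd = 0.25,
                         effects = NULL) {
  n <- n_control + n_autism
  ids <- sprintf("s%03d", seq_len(n))
  grp <- rep(c("control", "autism"), c(n_control, n_autism))
  li <- connections[rep(seq_len(nrow(connections)), times = n), ]
  li$subject_id <- rep(ids, each = nrow(connections))
  li$li <- rnorm(nrow(li), sd = li_sd)
  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      sel <- li$connection == effects$connection[i] &
        rep(grp, each = nrow(connections)) == effects$group[i]
      li$li[sel] <- li$li[sel] + effects$shift[i]
    }
  }
  list(li = tibble::as_tibble(li),
       groups = tibble::tibble(subject_id = ids, group = grp))
}
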