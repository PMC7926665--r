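# Shared helpers for the test suite.

# A small deterministic field stack reused across tests.
small_fields <- function(n_days = 6, seed = 101, ...) {
  generate_fields(field_params(grid = pm_grid(nx = 12, ny = 12, cell_size = 2),
                               n_days = n_days, seed = seed, ...))
}

# A tiny cohort on a given field stack.
small_cohort <- function(fields, n = 20, n_days = 6, seed = 202, ...) {
  generate_cohort(cohort_params(n_participants = n, n_days = n_days,
                                seed = seed, ...), fields)
}

# Brute-force Eq.-1 oracle: radius of gyration computed directly from the
# definition, independently of the package implementation.
rog_oracle <- function(place_x, place_y, n_k) {
  N <- sum(n_k)
  cx <- sum(n_k * place_x) / N
  cy <- sum(n_k * place_y) / N
  sqrt(sum(n_k * ((place_x - cx)^2 + (place_y - cy)^2)) / N)
}

# Independent ordinary-kriging solve in plain linear algebra: semivariance
# formulation with a Lagrange multiplier, solved with base::solve().
ok_oracle <- function(sx, sy, sz, px, py, vm) {
  n <- length(sx)
  D <- as.matrix(dist(cbind(sx, sy)))
  G <- apply(D, c(1, 2), function(h) semivariance(vm, h))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  h0 <- sqrt((sx - px)^2 + (sy - py)^2)
  g0 <- vapply(h0, function(h) semivariance(vm, h), numeric(1))
  sol <- solve(A, c(g0, 1))
  w <- sol[seq_len(n)]
  list(pred = sum(w * sz), var = sum(w * g0) + sol[n + 1], weights = w)
}

# A one-day visit table.
visits_df <- function(x, y, n_k, t_h, pid = "p1", date = as.Date("2016-12-01")) {
  data.frame(participant_id = pid, date = date,
             place_x = x, place_y = y, n_k = n_k, t_h = t_h)
}
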