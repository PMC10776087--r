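# Independent oracles and small fixture builders shared across tests.

# Brute-force Watson U2: evaluates the empirical cumulative fractions by
# direct counting at every pooled observation, independently of the
# cumulative-sweep implementation in the package.
watson_u2_oracle <- function(s1, s2) {
  s1 <- s1 %% 1
  s2 <- s2 %% 1
  n1 <- length(s1)
  n2 <- length(s2)
  N <- n1 + n2
  pts <- sort(c(s1, s2))
  d <- vapply(pts, function(t) sum(s1 <= t) / n1 - sum(s2 <= t) / n2,
              numeric(1))
  n1 * n2 / N^2 * (sum(d^2) - sum(d)^2 / N)
}

# Hand-arithmetic two-proportion z, written from the textbook formulas.
two_prop_oracle <- function(x1, n1, x2, n2, variant) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  if (variant == "pooled") {
    pb <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pb * (1 - pb) / n1 + pb * (1 - pb) / n2)
  } else {
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  (p2 - p1) / se
}

# Minimal single-pass footfall table builder.
make_events <- function(limb, contact, liftoff, x = contact * 10, y = 0,
                        placement = "plantar") {
  tibble::tibble(animal = 1L, timepoint = "tp", pass_id = 1L,
                 limb = limb, contact_time = contact, liftoff_time = liftoff,
                 x = x, y = y, placement = placement)
}

# Alternating four-limb pass with an exact hindlimb phase of `phi_rh`.
make_alternating_pass <- function(n_steps = 5, stride = 0.4, phi_rh = 0.5) {
  lh_t <- 0.5 + stride * (0:(n_steps))
  rh_t <- lh_t[seq_len(n_steps)] + phi_rh * stride
  dplyr::bind_rows(
    make_events("LH", lh_t, lh_t + 0.6 * stride, x = lh_t * 30, y = 2),
    make_events("RH", rh_t, rh_t + 0.6 * stride, x = rh_t * 30, y = -2)
  )
}

tiny_sim_config <- function(...) {
  sim_config(n_animals = 2L, passes_per_animal = 2L, steps_per_pass = 6L, ...)
}
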