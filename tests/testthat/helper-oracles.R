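## independent oracles and hand-built fixtures used across the suite

## hand-built ground-truth segment
make_truth <- function(length_um, positions, diameters,
                       birth = -1L, death = NA_integer_, classes = NULL,
                       schedule = study_schedule(), segment_id = "fix1",
                       mouse_id = "m1", genotype = "WT") {
  n <- length(positions)
  birth <- rep_len(as.integer(birth), n)
  death <- rep_len(as.integer(death), n)
  if (is.null(classes)) classes <- ifelse(diameters > 2, "alpha", "beta")
  boutons <- data.frame(
    bouton_id = sprintf("%s_b%03d", segment_id, seq_len(n)),
    class = classes, diameter_um = diameters,
    arc_position_um = positions, birth_day = birth, death_day = death)
  structure(list(segment_id = segment_id, mouse_id = mouse_id,
                 genotype = genotype, length_um = length_um,
                 schedule = schedule, boutons = boutons, seed = 0L),
            class = "segment_truth")
}

quiet_spec <- function(...) {
  imaging_spec(noise_model = "none", slow_drift_amplitude = 0,
               fast_jitter_amplitude = 0, ...)
}

## exact two-sided Mann-Whitney p by full enumeration of label assignments
mw_enum_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  n <- length(pool)
  u_of <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  ctr <- n1 * (n - n1) / 2
  mean(abs(us - ctr) >= abs(u_obs - ctr) - 1e-9)
}

## optimal (min-total-distance, max-cardinality) assignment by brute force
match_optimal <- function(a, b, tolerance = 2) {
  best <- list(card = -1, cost = Inf, links = NULL)
  recurse <- function(i, used_j, links, cost) {
    if (i > length(a)) {
      card <- nrow(links)
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12))
        best <<- list(card = card, cost = cost, links = links)
      return()
    }
    ## leave a[i] unmatched
    recurse(i + 1, used_j, links, cost)
    for (j in seq_along(b)) {
      d <- abs(a[i] - b[j])
      if (!used_j[j] && d <= tolerance) {
        used_j[j] <- TRUE
        recurse(i + 1, used_j, rbind(links, data.frame(i = i, j = j)),
                cost + d)
        used_j[j] <- FALSE
      }
    }
  }
  recurse(1, logical(length(b)), data.frame(i = integer(), j = integer()),
          0)
  lk <- best$links
  if (!is.null(lk) && nrow(lk)) lk[order(lk$i), , drop = FALSE] else lk
}

## brute-force recount of every turnover statistic for one segment,
## straight from the ground-truth presence sets (independent of the
## tracker/statistics code paths)
recount_segment <- function(seg, schedule = study_schedule()) {
  days <- schedule$imaging_days
  b <- seg$boutons[seg$boutons$class == "beta", , drop = FALSE]
  ids <- function(d) b$bouton_id[bouton_present(b, d)]
  P0 <- ids(days[1]); P1 <- ids(days[2]); P2 <- ids(days[3])
  obs <- union(P0, union(P1, P2))
  n <- length(obs)
  a <- seg$boutons[seg$boutons$class == "alpha", , drop = FALSE]
  idsa <- function(d) a$bouton_id[bouton_present(a, d)]
  A1 <- idsa(days[2]); A2 <- idsa(days[3])
  list(
    n_observed = n,
    elimination_training = length(setdiff(P0, P1)) / n,
    elimination_rest = length(setdiff(intersect(P0, P1), P2)) / n,
    elimination_rest_all = length(setdiff(P1, P2)) / n,
    formation_training = length(setdiff(P1, P0)) / n,
    formation_rest = length(setdiff(setdiff(P2, P1), P0)) / n,
    survival_d4 = length(intersect(P0, P1)) / length(P0),
    survival_d8 = length(intersect(P0, P2)) / length(P0),
    stabilization = length(intersect(setdiff(P1, P0), P2)) /
      length(setdiff(P1, P0)),
    tor_beta_rest = (length(setdiff(P2, P1)) + length(setdiff(P1, P2))) /
      (2 * length(P1)),
    tor_alpha_rest = (length(setdiff(A2, A1)) + length(setdiff(A1, A2))) /
      (2 * length(A1)))
}
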