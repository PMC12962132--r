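# Small fixtures built in code, shared across test files.

# A call table with two tight same-day clusters 1 km apart:
# cluster A holds IDs [A, A, A, B], cluster B holds [C, C].
two_cluster_calls <- function() {
  data.frame(call_id = as.character(1:6),
             x = c(0, 5, 10, 7, 1000, 1003),
             y = c(0, 3, 1, 2, 0, 2),
             day = 1L,
             predicted_id = c("A", "A", "A", "B", "C", "C"),
             stringsAsFactors = FALSE)
}

# n isolated same-day pairs of calls, pairs far apart, both members
# sharing coordinates; IDs assigned by the caller.
paired_calls <- function(n_pairs, ids) {
  data.frame(call_id = as.character(seq_len(2 * n_pairs)),
             x = rep(seq_len(n_pairs) * 10000, each = 2),
             y = 0,
             day = 1L,
             predicted_id = ids,
             stringsAsFactors = FALSE)
}

# Unit-square home range polygon.
square_polygon <- function(id = "sq", xmin = 0, xmax = 1, ymin = 0, ymax = 1) {
  homerange_polygon(id, cbind(c(xmin, xmax, xmax, xmin),
                              c(ymin, ymin, ymax, ymax)))
}

as_homeranges <- function(...) {
  polys <- list(...)
  names(polys) <- vapply(polys, `[[`, character(1), "range_id")
  structure(polys, class = "aiid_homeranges")
}

# Independent brute-force locality metrics: literal per-call double loop
# over pairwise distances, used as the oracle for the grouped
# implementation. Lenient tie rule.
brute_locality <- function(calls, radius) {
  n <- nrow(calls)
  consistent <- rep(NA, n); specific <- rep(NA, n)
  for (i in seq_len(n)) {
    nb <- c(); far <- c()
    for (j in seq_len(n)) {
      if (i == j || calls$day[j] != calls$day[i]) next
      d <- sqrt((calls$x[i] - calls$x[j])^2 + (calls$y[i] - calls$y[j])^2)
      if (d <= radius) nb <- c(nb, j) else far <- c(far, j)
    }
    if (length(nb) > 0) {
      cnt <- table(calls$predicted_id[nb])
      consistent[i] <- (calls$predicted_id[i] %in% names(cnt)) &&
        cnt[[calls$predicted_id[i]]] == max(cnt)
    }
    if (length(far) > 0)
      specific[i] <- sum(calls$predicted_id[nb] == calls$predicted_id[i]) >
        sum(calls$predicted_id[far] == calls$predicted_id[i])
  }
  ev <- !is.na(consistent) | !is.na(specific)
  fail <- (!is.na(consistent) & !consistent) | (!is.na(specific) & !specific)
  list(consistency = mean(consistent, na.rm = TRUE),
       specificity = mean(specific, na.rm = TRUE),
       accuracy_count = 1 - sum(fail) / sum(ev))
}

# Random call table for property tests.
random_calls <- function(n, n_ids = 3, n_days = 2, span = 300) {
  data.frame(call_id = as.character(seq_len(n)),
             x = runif(n, 0, span), y = runif(n, 0, span),
             day = sample.int(n_days, n, replace = TRUE),
             predicted_id = sample(LETTERS[seq_len(n_ids)], n, replace = TRUE),
             stringsAsFactors = FALSE)
}
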