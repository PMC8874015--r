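#' Constrained random-walk surrogate series
#'
#' Generates a synthetic series that preserves the ordinal transition
#' dynamics of the source network, per the constrained-walk idea: a random
#' walker moves over the OPN sampling successors in proportion to the edge
#' probabilities, restricted to overlap-consistent transitions (the
#' successor's leading d-1 ranks must be order-compatible with the
#' predecessor's trailing d-1 ranks). Values are emitted so that each
#' pattern of the walk is realized by an actual window of the output: the
#' new sample is drawn from the empirical values observed at the final
#' position of the successor's windows in `cloud`, restricted to the value
#' bracket its rank demands (bracket midpoint if no empirical value fits).
#'
#' With `lag = 1` consecutive windows genuinely share d-1 samples, the
#' constraint is exact, and re-embedding the surrogate with the generating
#' (d, tau) reproduces the walk's pattern sequence — and hence the source
#' transition probabilities — as the length grows. With `lag > 1`
#' consecutive windows share no samples; the constraint is then a heuristic
#' and realized window patterns can deviate from the walk (see the methods
#' vignette).
#'
#' If the walk reaches a node without outgoing edges it restarts from a
#' visit-frequency-weighted node (reported via a message and counted in the
#' `restarts` attribute).
#'
#' @param net source `opn` built from `cloud`'s embedding.
#' @param cloud the `tsn_cloud` the OPN's symbols were derived from.
#' @param length number of samples to generate (>= the embedding span + 1).
#' @param seed integer seed; the output is fully reproducible given it.
#' @return tibble of class `tsn_surrogate` with columns `time` and `value`;
#'   attributes `symbols` (the walk's pattern labels, one per window) and
#'   `restarts`.
#' @export
surrogate_series <- function(net, cloud, length, seed) {
  stopifnot(inherits(net, "opn"))
  d <- attr(cloud, "dim_embed") %||% net$params$dim
  tau <- attr(cloud, "lag") %||% net$params$lag
  if (is.null(d) || is.null(tau)) {
    stop("embedding parameters unknown; build the OPN from permutation_embed()",
         call. = FALSE)
  }
  span <- (d - 1L) * tau
  length <- check_count(length, "length", min = span + 1L)
  seed <- check_count(seed, "seed", min = 0L)
  pts <- cloud_matrix(cloud)
  if (ncol(pts) != d) stop("cloud dimension does not match the OPN", call. = FALSE)
  cloud_labels <- apply(pts, 1L, function(v) pattern_label(rank(v, ties.method = "first")))
  # empirical final-position values per pattern, for value emission
  finals <- split(pts[, d], cloud_labels)
  ranks <- lapply(net$patterns, pattern_ranks)
  names(ranks) <- net$patterns
  prefix_ord <- vapply(ranks, function(r) pattern_label(rank(r[-length(r)], ties.method = "first")),
                       character(1))
  suffix_ord <- vapply(ranks, function(r) pattern_label(rank(r[-1L], ties.method = "first")),
                       character(1))
  visits <- net$visits / sum(net$visits)

  withr::with_seed(seed, {
    n_steps <- length - span
    y <- numeric(length)
    walk <- character(n_steps)
    restarts <- 0L
    # seed samples: an empirical window of a visit-weighted start pattern
    start <- sample(net$patterns, 1L, prob = visits)
    cand_rows <- which(cloud_labels == start)
    seed_vec <- pts[sample(cand_rows, 1L), ]
    for (a in seq_len(d - 1L)) y[1L + (a - 1L) * tau] <- seed_vec[a]
    if (tau > 1L) {
      # off-stride seed positions, drawn from the empirical marginal
      open <- setdiff(seq_len(span), 1L + (seq_len(d - 1L) - 1L) * tau)
      y[open] <- sample(pts[, 1L], base::length(open), replace = TRUE)
    }
    cur <- NA_character_
    for (s in seq_len(n_steps)) {
      widx <- s + (seq_len(d - 1L) - 1L) * tau # first d-1 window positions
      have <- y[widx]
      need <- pattern_label(rank(have, ties.method = "first"))
      if (is.na(cur)) {
        cand <- net$patterns[prefix_ord == need]
        wts <- visits[prefix_ord == need]
      } else {
        out <- net$probs[cur, ]
        ok <- out > 0 & suffix_ord[cur] == prefix_ord & prefix_ord == need
        cand <- net$patterns[ok]
        wts <- out[ok]
        if (base::length(cand) == 0L) { # dead end: restart from visit weights
          restarts <- restarts + 1L
          cand <- net$patterns[prefix_ord == need]
          wts <- visits[prefix_ord == need]
        }
      }
      if (base::length(cand) == 0L) { # prefix order unseen in the source
        restarts <- restarts + 1L
        cand <- net$patterns
        wts <- visits
      }
      nxt <- if (base::length(cand) == 1L) cand else sample(cand, 1L, prob = wts)
      walk[s] <- nxt
      y[s + span] <- emit_value(ranks[[nxt]][d], have, finals[[nxt]])
      cur <- nxt
    }
    if (restarts > 0L) {
      message("constrained walk restarted ", restarts, " time(s) at dead ends")
    }
    out <- tibble::tibble(time = seq_len(length), value = y)
    structure(out, symbols = walk, restarts = restarts,
              dim_embed = d, lag = tau,
              class = c("tsn_surrogate", class(out)))
  })
}

#' @rdname surrogate_series
#' @export
constrained_walk <- surrogate_series

# Choose a value whose rank among c(have, value) is `rank_new`, preferring
# empirical candidates inside the admissible bracket.
emit_value <- function(rank_new, have, candidates) {
  s <- sort(have)
  k <- length(have)
  lo <- if (rank_new == 1L) -Inf else s[rank_new - 1L]
  hi <- if (rank_new == k + 1L) Inf else s[rank_new]
  # ties.method = "first": the new (later-index) value must be strictly
  # above `lo` to outrank it, and strictly below `hi` to stay under it;
  # equality with `hi` would still rank below it, but keep strict for
  # numerical sanity.
  fit <- candidates[candidates > lo & candidates < hi]
  if (length(fit) > 0L) return(if (length(fit) == 1L) fit else sample(fit, 1L))
  spread <- if (k > 1L) max(s) - min(s) else abs(s[1L])
  pad <- max(spread, 1e-8)
  if (is.infinite(lo)) return(hi - pad)
  if (is.infinite(hi)) return(lo + pad)
  (lo + hi) / 2
}
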