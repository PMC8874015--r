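#' Time-delay embedding of a scalar series
#'
#' Reconstructs a d-dimensional state-space trajectory from a single channel
#' by the standard delay map: point i is
#' \eqn{(x_i, x_{i+\tau}, \dots, x_{i+(d-1)\tau})}. The number of embedded
#' points is `length(x) - (dim - 1) * lag`.
#'
#' @param x single-channel series: numeric vector or data frame (see
#'   [read_timeseries()]).
#' @param dim embedding dimension d, integer >= 2.
#' @param lag embedding delay tau, integer >= 1 (in samples).
#' @param channel optional channel name when `x` is a multi-column frame.
#' @return A tibble of class `tsn_cloud` with a `time` column (index of each
#'   point's first element, 1-based) and coordinate columns `x1..xd`.
#'   Attributes `dim` and `lag` record the embedding.
#' @examples
#' delay_embed(c(0.1, 0.3, 1.2, 0.2, 0.8, 1.7, 1.3, 0.4, 0.2), dim = 3, lag = 2)
#' @export
delay_embed <- function(x, dim, lag = 1L, channel = NULL) {
  v <- ts_values(x, channel)
  d <- check_count(dim, "dim", min = 2L)
  tau <- check_count(lag, "lag", min = 1L)
  n <- length(v)
  span <- (d - 1L) * tau
  if (span >= n) {
    stop("series too short for dim = ", d, ", lag = ", tau,
         ": need at least ", span + 1L, " samples, got ", n, call. = FALSE)
  }
  m <- n - span
  pts <- vapply(seq_len(d), function(k) v[seq_len(m) + (k - 1L) * tau],
                numeric(m))
  if (m == 1L) pts <- matrix(pts, nrow = 1L)
  colnames(pts) <- paste0("x", seq_len(d))
  out <- tibble::as_tibble(as.data.frame(pts))
  out <- tibble::add_column(out, time = seq_len(m), .before = 1L)
  new_cloud(out, dim = d, lag = tau)
}

new_cloud <- function(tbl, dim, lag) {
  structure(tbl, dim_embed = as.integer(dim), lag = as.integer(lag),
            class = c("tsn_cloud", class(tibble::as_tibble(tbl))))
}

#' Extract the coordinate matrix of a point cloud
#'
#' @param cloud a `tsn_cloud` tibble from [delay_embed()], or any data frame
#'   whose numeric non-`time` columns are state-vector coordinates (a
#'   multichannel recording used directly as native state vectors), or a
#'   numeric matrix.
#' @return numeric matrix, one row per state vector.
#' @export
cloud_matrix <- function(cloud) {
  if (is.matrix(cloud)) {
    storage.mode(cloud) <- "double"
    return(cloud)
  }
  if (!is.data.frame(cloud)) stop("not a point cloud", call. = FALSE)
  cols <- setdiff(names(cloud)[vapply(cloud, is.numeric, logical(1))], "time")
  if (length(cols) == 0L) stop("no coordinate columns found", call. = FALSE)
  as.matrix(cloud[cols])
}

cloud_times <- function(cloud) {
  if (is.data.frame(cloud) && "time" %in% names(cloud)) {
    return(cloud[["time"]])
  }
  seq_len(nrow(cloud_matrix(cloud)))
}

#' Ordinal pattern (rank word) of a state vector
#'
#' Assigns ascending ranks: element k receives rank
#' 1 + (number of elements strictly smaller than it), with ties broken by the
#' earlier index taking the lower rank (the Bandt--Pompe convention). The
#' result is always a permutation of 1..d.
#'
#' @param v numeric vector (one embedded state vector).
#' @return integer vector of ranks of class `ordinal_pattern`, with a
#'   `label` attribute: ranks concatenated as digits for d <= 9
#'   (e.g. `"132"`), dash-separated above that.
#' @examples
#' ordinal_pattern(c(0.1, 1.2, 0.8)) # ranks 1 3 2, label "132"
#' @export
ordinal_pattern <- function(v) {
  if (length(v) == 0L) stop("empty vector", call. = FALSE)
  if (anyNA(v)) stop("missing values in state vector", call. = FALSE)
  r <- as.integer(rank(v, ties.method = "first"))
  structure(r, label = pattern_label(r), class = "ordinal_pattern")
}

#' @export
print.ordinal_pattern <- function(x, ...) {
  cat("<ordinal pattern>", attr(x, "label"), "\n")
  invisible(x)
}

#' Render a rank vector as a pattern label
#' @param ranks integer permutation of 1..d.
#' @return character label (`"132"` style; dash-separated when d > 9).
#' @export
pattern_label <- function(ranks) {
  sep <- if (length(ranks) > 9L) "-" else ""
  paste(as.integer(ranks), collapse = sep)
}

#' Recover ranks from a pattern label
#' @param label character label produced by [pattern_label()].
#' @return integer rank vector.
#' @export
pattern_ranks <- function(label) {
  if (grepl("-", label, fixed = TRUE)) {
    as.integer(strsplit(label, "-", fixed = TRUE)[[1L]])
  } else {
    as.integer(strsplit(label, "", fixed = TRUE)[[1L]])
  }
}

#' Permutation embedding of a scalar series
#'
#' Delay-embeds the series and maps every embedded vector to its ordinal
#' pattern, producing the symbolic (rank-word) sequence that ordinal
#' partition networks are built from.
#'
#' @inheritParams delay_embed
#' @return A tibble of class `tsn_symbols` with columns `time` (index of the
#'   window's first sample) and `pattern` (rank-word label). Attributes
#'   `dim` and `lag` record the embedding.
#' @examples
#' permutation_embed(c(0.1, 0.3, 1.2, 0.2, 0.8, 1.7, 1.3, 0.4, 0.2),
#'                   dim = 3, lag = 2)
#' @export
permutation_embed <- function(x, dim, lag = 1L, channel = NULL) {
  cloud <- delay_embed(x, dim = dim, lag = lag, channel = channel)
  pts <- cloud_matrix(cloud)
  labels <- apply(pts, 1L, function(v) attr(ordinal_pattern(v), "label"))
  out <- tibble::tibble(time = cloud$time, pattern = labels)
  structure(out, dim_embed = attr(cloud, "dim_embed"),
            lag = attr(cloud, "lag"),
            class = c("tsn_symbols", class(out)))
}

#' @rdname permutation_embed
#' @export
permutation_embedding <- permutation_embed

symbol_labels <- function(symbols) {
  if (is.data.frame(symbols)) symbols[["pattern"]] else as.character(symbols)
}

#' Select an embedding delay
#'
#' Two standard heuristics for the delay tau used by permutation and delay
#' embeddings: the first non-positive integer lag of the sample
#' autocorrelation function, or the first local minimum of the binned
#' auto-mutual information (sensitive to nonlinear dependence).
#'
#' @inheritParams delay_embed
#' @param strategy `"acf-first-zero"` or `"ami-first-min"`.
#' @param max_lag largest lag examined (must be below the series length).
#' @param n_bins bins for the auto-mutual information histogram; default
#'   `ceiling(sqrt(n))` capped at 64.
#' @return integer lag. If no lag qualifies, `max_lag` is returned with a
#'   warning.
#' @export
select_lag <- function(x, strategy = c("acf-first-zero", "ami-first-min"),
                       max_lag = NULL, n_bins = NULL, channel = NULL) {
  strategy <- match.arg(strategy)
  v <- ts_values(x, channel)
  n <- length(v)
  if (stats::sd(v) == 0) {
    stop("constant series: autocorrelation is undefined", call. = FALSE)
  }
  if (is.null(max_lag)) max_lag <- min(n - 1L, max(20L, floor(n / 4)))
  max_lag <- check_count(max_lag, "max_lag", min = 1L)
  if (max_lag >= n) stop("max_lag must be below the series length", call. = FALSE)

  if (strategy == "acf-first-zero") {
    rho <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf[-1L]
    # first non-positive lag; at a sign crossing the integer nearer zero is
    # taken, so the O(1/n) positive bias of the sample ACF at an exact
    # quarter-period does not shift the result by one lag
    hit <- which(rho <= 0 |
                   (rho > 0 & dplyr::lead(rho, default = 1) < 0 &
                      rho < abs(dplyr::lead(rho, default = 1))))
  } else {
    ami <- vapply(seq_len(max_lag), function(l) {
      auto_mutual_information(v, lag = l, n_bins = n_bins)
    }, numeric(1))
    # first interior local minimum of the AMI curve
    hit <- which(diff(sign(diff(c(Inf, ami, Inf)))) == 2) # indices of minima
    hit <- hit[hit < max_lag] # endpoint is not a local minimum
  }
  if (length(hit) == 0L) {
    warning("no qualifying lag found up to max_lag = ", max_lag,
            "; returning max_lag", call. = FALSE)
    return(max_lag)
  }
  as.integer(hit[1L])
}

#' @rdname select_lag
#' @export
optimal_lag <- select_lag

#' Binned auto-mutual information
#'
#' Plug-in mutual information (natural log) between \eqn{x_t} and
#' \eqn{x_{t+lag}} estimated on an equal-width 2-D histogram. A constant
#' series occupies a single bin and returns 0 by convention.
#'
#' @inheritParams select_lag
#' @param lag delay in samples, `0 <= lag < length(x)`.
#' @return non-negative mutual information in nats.
#' @export
auto_mutual_information <- function(x, lag, n_bins = NULL, channel = NULL) {
  v <- ts_values(x, channel)
  lag <- check_count(lag, "lag", min = 0L)
  n <- length(v)
  if (lag >= n) stop("lag must be below the series length", call. = FALSE)
  if (is.null(n_bins)) n_bins <- min(64L, ceiling(sqrt(n)))
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  a <- v[seq_len(n - lag)]
  b <- v[seq_len(n - lag) + lag]
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  ia <- findInterval(a, brk, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, brk, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(ia, ib) / length(a)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}
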