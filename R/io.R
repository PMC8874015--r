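#' Read a time series from a delimited text file
#'
#' Reads CSV or TSV (delimiter sniffed from the first line) with one column
#' per channel and an optional header. A time column may be named for
#' irregularly sampled data; it is renamed `time` in the output. Non-numeric
#' cells and files with fewer than 2 rows are rejected with explicit
#' locations. Rows with missing values are rejected by default, or dropped
#' with a warning when `na_action = "drop"` (recurrence networks need no
#' regular sampling, so dropping rows is legitimate there).
#'
#' @param path file path.
#' @param time_column optional name (or 1-based index) of the column holding
#'   sample times.
#' @param na_action `"error"` (default) or `"drop"`.
#' @return tibble with channels in column order and, if requested, a strictly
#'   increasing `time` column first.
#' @export
read_timeseries <- function(path, time_column = NULL,
                            na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  has_header <- !all(
    vapply(strsplit(first, delim, fixed = TRUE)[[1L]],
           function(f) !is.na(suppressWarnings(as.numeric(f))), logical(1)))
  tbl <- readr::read_delim(path, delim = delim, col_names = has_header,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  if (nrow(tbl) < 2L) stop("need at least 2 rows, got ", nrow(tbl), call. = FALSE)
  if (!has_header) names(tbl) <- paste0("V", seq_along(tbl))
  num <- lapply(tbl, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(tbl[[j]]) & tbl[[j]] != "")
    if (length(bad) > 0L) {
      stop("non-numeric cell at row ", bad[1L], ", column '", names(tbl)[j],
           "'", call. = FALSE)
    }
  }
  out <- tibble::as_tibble(num)
  miss <- which(!stats::complete.cases(out))
  if (length(miss) > 0L) {
    if (na_action == "error") {
      stop("missing value at row ", miss[1L], "; use na_action = \"drop\" ",
           "to discard incomplete rows", call. = FALSE)
    }
    warning("dropped ", length(miss), " row(s) with missing values",
            call. = FALSE)
    out <- out[-miss, ]
  }
  if (!is.null(time_column)) {
    nm <- if (is.numeric(time_column)) names(out)[time_column] else time_column
    if (!nm %in% names(out)) {
      stop("time column '", nm, "' not found", call. = FALSE)
    }
    names(out)[names(out) == nm] <- "time"
    out <- dplyr::relocate(out, "time")
    if (is.unsorted(out$time, strictly = TRUE)) {
      stop("time column must be strictly increasing", call. = FALSE)
    }
  }
  out
}

#' Write a state network to disk
#'
#' Three plain-text formats. `"edgelist"`: TSV with header
#' `source  target  weight`, node ids the 0-based time index for recurrence
#' and visibility networks and the pattern label for OPNs; unweighted edges
#' are written with weight 1; weights carry 12 significant digits so test-
#' scale round trips are exact. `"graphml"`: igraph's GraphML writer, with
#' node attributes (time index or visit count) and edge weights.
#' `"adjacency-csv"`: dense adjacency (probabilities for OPNs, weights or
#' 0/1 otherwise) with node ids as row and column labels.
#'
#' @param net a `state_network`.
#' @param path output file path.
#' @param format `"edgelist"`, `"graphml"`, or `"adjacency-csv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path,
                          format = c("edgelist", "graphml", "adjacency-csv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "state_network"))
  g <- net$graph
  ids <- network_ids(net)
  if (format == "graphml") {
    gg <- g
    igraph::V(gg)$name <- ids
    igraph::write_graph(gg, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- if ("weight" %in% igraph::edge_attr_names(g)) {
      igraph::E(g)$weight
    } else {
      rep(1, nrow(el))
    }
    tbl <- tibble::tibble(source = ids[el[, 1L]], target = ids[el[, 2L]],
                          weight = signif(w, 12))
    readr::write_tsv(tbl, path, progress = FALSE)
    return(invisible(path))
  }
  adj <- if (inherits(net, "opn")) {
    net$probs
  } else {
    as.matrix(igraph::as_adjacency_matrix(
      g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
      sparse = FALSE))
  }
  dimnames(adj) <- list(ids, ids)
  df <- tibble::as_tibble(as.data.frame(signif(adj, 12)), .name_repair = "minimal")
  df <- tibble::add_column(df, node = ids, .before = 1L)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# 0-based time indices for sample-indexed networks, pattern labels for OPNs
network_ids <- function(net) {
  if (inherits(net, "opn")) return(net$patterns)
  as.character(as.integer(igraph::V(net$graph)$time) - 1L)
}

#' Read back a written edge list
#'
#' Companion to [write_network()]'s `"edgelist"` format; returns the edge
#' multiset as a tibble (`source`, `target`, `weight`) for round-trip
#' checks and downstream tools.
#'
#' @param path TSV edge-list path.
#' @return tibble with character ids and numeric weights.
#' @export
read_network_edgelist <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(),
    target = readr::col_character(),
    weight = readr::col_double()), progress = FALSE)
}
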