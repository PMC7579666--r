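# Historical encoding: parse catastrophe case lists (chains-of-events
# recorded as directed peril pairs) and build the empirical binary
# adjacency matrix over the peril taxonomy.

#' Parse a catastrophe case file
#'
#' Reads a TSV with columns `case_id`, `name`, `country`, `trigger` and a
#' pair column that is either `pairs` (tokens `SRC>TGT` separated by `|`)
#' or `encoding` (the raw `"(XX, YY); (ZZ, WW)"` syntax used in published
#' case tables; `,` and `;` both accepted as the in-pair separator). Pair
#' tokens are normalized through [resolve_id()] (uppercasing and the
#' `ES -> EC` alias); duplicates within a case are preserved as listed.
#'
#' @param path Case file path; defaults to the packaged transcription of
#'   29 historical catastrophes.
#' @param registry A `peril_registry` (default [load_taxonomy()]).
#' @return List of `catastrophe_case` objects, each with fields `case_id`,
#'   `name`, `country`, `trigger`, `pairs` (two-column character matrix,
#'   one row per ordered source-target pair, in listed order).
#' @examples
#' cases <- suppressWarnings(parse_case_file())
#' length(cases)
#' cases[[1]]$pairs
#' @export
parse_case_file <- function(path = NULL, registry = load_taxonomy()) {
  if (is.null(path)) {
    path <- system.file("extdata", "catastrophes.tsv", package = "cascadyn",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                           fileEncoding = "UTF-8")
  if (nrow(tab) == 0L) return(list())
  required <- c("case_id", "name", "country", "trigger")
  if (!all(required %in% names(tab)) ||
      !any(c("pairs", "encoding") %in% names(tab))) {
    stop("case file ", path, " must have columns ",
         paste(required, collapse = ", "),
         " and one of 'pairs' or 'encoding'", call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    raw <- if ("pairs" %in% names(tab) && nzchar(row$pairs %||% "")) {
      parse_pipe_pairs(row$pairs, row$case_id)
    } else if ("encoding" %in% names(tab) && nzchar(row$encoding %||% "")) {
      parse_raw_encoding(row$encoding, row$case_id)
    } else {
      matrix(character(), ncol = 2L)
    }
    if (nrow(raw) == 0L) {
      stop("case '", row$case_id, "': empty pair list", call. = FALSE)
    }
    pairs <- cbind(resolve_id(raw[, 1L], registry, context = row$case_id),
                   resolve_id(raw[, 2L], registry, context = row$case_id))
    colnames(pairs) <- c("from", "to")
    structure(list(case_id = row$case_id, name = row$name,
                   country = row$country,
                   trigger = resolve_id(row$trigger, registry,
                                        context = row$case_id),
                   pairs = pairs),
              class = "catastrophe_case")
  })
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# "EQ>FL|FL>CF" dialect
parse_pipe_pairs <- function(text, case_id) {
  toks <- strsplit(text, "|", fixed = TRUE)[[1]]
  toks <- trimws(toks[nzchar(trimws(toks))])
  out <- lapply(toks, function(t) {
    parts <- trimws(strsplit(t, ">", fixed = TRUE)[[1]])
    if (length(parts) != 2L || !all(nzchar(parts))) {
      stop("case '", case_id, "': malformed pair token '", t, "'",
           call. = FALSE)
    }
    parts
  })
  do.call(rbind, c(out, list(matrix(character(), ncol = 2L))))
}

# raw "(EQ, FL); (FL; CF)" dialect: pairs are parenthesized, the in-pair
# separator is "," or ";" with optional whitespace
parse_raw_encoding <- function(text, case_id) {
  groups <- regmatches(text, gregexpr("\\(([^()]*)\\)", text))[[1]]
  out <- lapply(groups, function(g) {
    inner <- sub("^\\(", "", sub("\\)$", "", g))
    parts <- trimws(strsplit(inner, "[,;]")[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L) {
      stop("case '", case_id, "': malformed pair '", g, "'", call. = FALSE)
    }
    parts
  })
  do.call(rbind, c(out, list(matrix(character(), ncol = 2L))))
}

#' @export
print.catastrophe_case <- function(x, ...) {
  cat(x$name, if (nzchar(x$country)) paste0("(", x$country, ")"),
      "- trigger", x$trigger, "-",
      paste(x$pairs[, 1L], x$pairs[, 2L], sep = ">", collapse = " "), "\n")
  invisible(x)
}

#' Write cases back to the tabular dialect
#'
#' Serializes a case list with pairs as `SRC>TGT` tokens separated by `|`,
#' the dialect [parse_case_file()] reads; round-tripping preserves pair
#' multisets and order.
#'
#' @param cases List of `catastrophe_case` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_case_file <- function(cases, path) {
  rows <- vapply(cases, function(cs) {
    paste(cs$case_id, cs$name, cs$country, cs$trigger,
          paste(cs$pairs[, 1L], cs$pairs[, 2L], sep = ">", collapse = "|"),
          sep = "\t")
  }, character(1))
  writeLines(c("case_id\tname\tcountry\ttrigger\tpairs", rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Build the empirical adjacency matrix from observed cases
#'
#' Binary encoding: entry (i, j) is `p` if the ordered pair was observed in
#' at least one case, 0 otherwise. Recurrence across cases does not raise
#' the probability (the matrix is an unweighted union of per-case pair
#' sets); the citing case ids per edge are retained in the `provenance`
#' attribute for reporting.
#'
#' @param cases List of `catastrophe_case` objects.
#' @param registry A `peril_registry` fixing the matrix order.
#' @param p Ad-hoc one-step probability assigned to observed pairs.
#' @param exclude_edges Optional character vector of `"SRC>TGT"` tokens to
#'   drop (e.g. `"MS>DI"` to exclude a singular rare interaction).
#' @return A `reduced_adjacency` over the full registry, with attribute
#'   `provenance`: a named list mapping `"SRC>TGT"` to citing case ids.
#' @export
build_empirical_adjacency <- function(cases, registry = load_taxonomy(),
                                      p = 0.1, exclude_edges = NULL) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("p must be a single probability in (0, 1)", call. = FALSE)
  }
  ids <- peril_ids(registry)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  prov <- list()
  for (cs in cases) {
    for (k in seq_len(nrow(cs$pairs))) {
      key <- paste0(cs$pairs[k, 1L], ">", cs$pairs[k, 2L])
      prov[[key]] <- unique(c(prov[[key]], cs$case_id))
    }
  }
  if (!is.null(exclude_edges)) prov[exclude_edges] <- NULL
  for (key in names(prov)) {
    st <- strsplit(key, ">", fixed = TRUE)[[1]]
    m[st[1L], st[2L]] <- p
  }
  a <- reduced_adjacency(m, labels = ids)
  attr(a, "provenance") <- prov
  a
}

#' Summary statistics of a case list
#'
#' @param cases List of `catastrophe_case` objects.
#' @return List with `n_cases`, `n_pairs` (pair tokens including
#'   duplicates), `n_distinct_pairs` (distinct ordered pairs), and
#'   `trigger_counts` (named integer vector of cases per trigger peril).
#' @export
case_statistics <- function(cases) {
  if (length(cases) == 0L) {
    return(list(n_cases = 0L, n_pairs = 0L, n_distinct_pairs = 0L,
                trigger_counts = integer()))
  }
  all_pairs <- do.call(rbind, lapply(cases, `[[`, "pairs"))
  keys <- paste0(all_pairs[, 1L], ">", all_pairs[, 2L])
  triggers <- vapply(cases, `[[`, character(1), "trigger")
  list(n_cases = length(cases),
       n_pairs = length(keys),
       n_distinct_pairs = length(unique(keys)),
       trigger_counts = table(triggers))
}
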