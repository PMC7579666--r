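# Peril taxonomy: the fixed catalogue of loss-generating event classes that
# fixes the index order of every matrix in the package.

.canonical_ids <- c(
  "EQ", "VE", "MS", "FL", "WS", "OS", "EW", "WF", "DI", "AI", "GS",
  "FI", "CF", "NF", "BI", "EC", "SU", "HD", "CO"
)

.natural_origins <- c(
  "geological/geomorphological", "hydrological", "meteorological",
  "biophysical/ecological", "extraterrestrial"
)
.anthropogenic_origins <- c("technological", "economical", "social")

# Token aliases applied by resolve_id(); "ES" is used in some case records
# for the economic-crisis peril catalogued as EC.
.id_aliases <- c(ES = "EC")

.cascadyn_env <- new.env(parent = emptyenv())

#' Load the peril taxonomy
#'
#' Reads the packaged catalogue of 19 peril classes (or a user-supplied
#' taxonomy in the same TSV dialect) and returns a validated registry whose
#' row order fixes the matrix index order used throughout the package.
#'
#' @param path Path to a taxonomy TSV with columns `id`, `name`, `origin`,
#'   `system` (`#` lines are comments). Defaults to the packaged 19-peril
#'   catalogue.
#' @return An object of class `peril_registry`: a list with elements
#'   `perils` (data frame in catalogue order), `n_perils`, and `canonical`
#'   (`TRUE` when the registry is exactly the packaged 19-peril catalogue;
#'   user extensions set it to `FALSE` and opt out of 19-peril checks).
#' @examples
#' reg <- load_taxonomy()
#' reg$n_perils
#' peril_index(reg, "EQ")
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "perils.tsv", package = "cascadyn",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                           fileEncoding = "UTF-8")
  required <- c("id", "name", "origin", "system")
  if (!all(required %in% names(tab))) {
    stop("taxonomy file ", path, " must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, required]
  if (anyDuplicated(tab$id)) {
    stop("taxonomy file has duplicated peril ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(grepl("^[A-Z]{2}$", tab$id))) {
    bad <- tab$id[!grepl("^[A-Z]{2}$", tab$id)]
    stop("peril ids must be exactly two uppercase letters; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  known <- c(.natural_origins, .anthropogenic_origins)
  if (!all(tab$origin %in% known)) {
    stop("unknown origin category: ",
         paste(setdiff(tab$origin, known), collapse = ", "), call. = FALSE)
  }
  expected_system <- ifelse(tab$origin %in% .natural_origins,
                            "natural", "anthropogenic")
  if (!identical(tab$system, expected_system)) {
    bad <- tab$id[tab$system != expected_system]
    stop("system label inconsistent with origin for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(perils = tab, n_perils = nrow(tab),
         canonical = identical(tab$id, .canonical_ids)),
    class = "peril_registry"
  )
}

#' @export
print.peril_registry <- function(x, ...) {
  cat("Peril registry:", x$n_perils, "perils",
      if (x$canonical) "(canonical catalogue)" else "(user extension)", "\n")
  cat(" natural:      ",
      paste(x$perils$id[x$perils$system == "natural"], collapse = " "), "\n")
  cat(" anthropogenic:",
      paste(x$perils$id[x$perils$system == "anthropogenic"], collapse = " "),
      "\n")
  invisible(x)
}

#' Peril ids of a registry, in matrix index order
#' @param registry A `peril_registry`.
#' @return Character vector of peril ids.
#' @export
peril_ids <- function(registry) registry$perils$id

#' Position of a peril id in the registry order
#' @param registry A `peril_registry`.
#' @param id Peril id (canonical, see [resolve_id()]).
#' @return Integer index (1-based).
#' @export
peril_index <- function(registry, id) {
  i <- match(id, registry$perils$id)
  if (anyNA(i)) {
    stop("unknown peril id: ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' System (natural/anthropogenic) of a peril
#' @inheritParams peril_index
#' @return Character vector, `"natural"` or `"anthropogenic"`.
#' @export
peril_system <- function(registry, id) {
  registry$perils$system[peril_index(registry, id)]
}

#' Resolve a raw peril token to its canonical id
#'
#' Uppercases, trims, and applies the alias map (currently `ES -> EC`, the
#' economic-crisis peril appearing under two spellings in case records).
#' The first aliased token per session raises a warning so normalization
#' events are auditable.
#'
#' @param token Raw identifier string from a case file.
#' @param registry A `peril_registry` to resolve against.
#' @param context Optional text (e.g. a case id) prepended to error messages.
#' @return The canonical peril id.
#' @export
resolve_id <- function(token, registry, context = NULL) {
  tok <- toupper(trimws(token))
  out <- character(length(tok))
  for (k in seq_along(tok)) {
    t1 <- tok[k]
    if (t1 %in% names(.id_aliases)) {
      canon <- .id_aliases[[t1]]
      flag <- paste0("aliased_", t1)
      if (!isTRUE(.cascadyn_env[[flag]])) {
        warning("token '", t1, "' aliased to '", canon,
                "' (economic-crisis peril); further uses are silent",
                call. = FALSE)
        .cascadyn_env[[flag]] <- TRUE
      }
      t1 <- canon
    }
    if (!t1 %in% registry$perils$id) {
      stop(if (!is.null(context)) paste0(context, ": "),
           "unknown peril token '", token[k], "'", call. = FALSE)
    }
    out[k] <- t1
  }
  out
}
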