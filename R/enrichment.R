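#' Read a metabolite-set library in GMT format
#'
#' Each line is \code{name <TAB> description <TAB> member1 <TAB> member2 ...}.
#' Duplicate members within a set are deduplicated; a line with fewer than
#' three fields is an error reporting the line number.
#'
#' @param path GMT file.
#' @return A list of class \code{metabolite_set_library}: \code{sets} (named
#'   list of member vectors) and \code{descriptions}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (ln in seq_along(lines)) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop(sprintf("malformed GMT line %d: expected name, description and at least one member", ln))
    nm <- parts[1L]
    if (nm %in% names(sets)) stop(sprintf("duplicate set name '%s' at line %d", nm, ln))
    sets[[nm]] <- unique(parts[-(1:2)])
    desc[nm] <- parts[2L]
  }
  structure(list(sets = sets, descriptions = desc),
            class = "metabolite_set_library")
}

#' Write a metabolite-set library in GMT format
#'
#' @param library a \code{metabolite_set_library} (or a named list of member
#'   vectors).
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(library, path) {
  sets <- if (inherits(library, "metabolite_set_library")) library$sets else library
  desc <- if (inherits(library, "metabolite_set_library")) library$descriptions else
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, if (is.na(desc[nm])) "" else desc[nm], sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a metabolite list
#'
#' For each set, intersects its members with the measured universe and tests
#' the overlap with the query via the hypergeometric upper tail
#' P(X >= k) where k is the query/set overlap, K the set size within the
#' universe, n the query size and N the universe size. Sets with no universe
#' overlap are not tested; BH adjustment runs over the tested sets.
#'
#' @param query character vector of metabolites of interest; must be a
#'   subset of \code{universe}.
#' @param universe character vector of all measured (annotated) metabolites.
#' @param library a \code{metabolite_set_library} from \code{\link{read_gmt}}
#'   or a named list of member vectors.
#' @return Data frame sorted by p-value with columns \code{set_name},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p_value},
#'   \code{p_adjusted}.
#' @export
ora <- function(query, universe, library) {
  sets <- if (inherits(library, "metabolite_set_library")) library$sets else library
  query <- unique(query); universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop(sprintf("query metabolites not in the universe: %s",
                 paste(outside, collapse = ", ")))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      p_adjusted = numeric()))
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_value, nrow(res))
  res[order(res$p_value), , drop = FALSE]
}
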