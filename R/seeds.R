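POLARIZATION_LEVELS <- c("M1", "M2", "unclassified")

new_seed_set <- function(drivers, provenance = "") {
  structure(list(drivers = drivers, provenance = provenance),
            class = "seed_set")
}

#' Construct a driver-gene set
#'
#' @param symbol Gene symbols.
#' @param polarization "M1", "M2" or "unclassified" (recycled).
#' @param evidence List of character vectors of evidence tags
#'   (literature, rtpcr, microarray, metabolite), or a comma-joined
#'   character vector.
#' @param weight Positive prior weights (recycled, default 1).
#' @param aliases Optional alias table ([read_alias_table()]).
#' @param provenance Free-text note.
#' @return A `seed_set`: drivers data.frame (symbol, polarization, evidence
#'   list-column, weight) with unique symbols; duplicates are merged by
#'   summing weights and unioning evidence.
#' @export
seed_set <- function(symbol, polarization = "unclassified",
                     evidence = "literature", weight = 1,
                     aliases = NULL, provenance = "") {
  symbol <- resolve_aliases(symbol, aliases)
  n <- length(symbol)
  polarization <- rep_len(as.character(polarization), n)
  bad <- !polarization %in% POLARIZATION_LEVELS
  if (any(bad)) {
    stop(sprintf("unknown polarization %s (row %d)",
                 dQuote(polarization[which(bad)[1L]]), which(bad)[1L]))
  }
  weight <- rep_len(as.numeric(weight), n)
  if (any(!is.finite(weight) | weight <= 0)) stop("driver weight must be > 0")
  if (is.character(evidence)) {
    evidence <- lapply(rep_len(evidence, n),
                       function(s) trimws(strsplit(s, ",")[[1]]))
  }
  evidence <- rep_len(evidence, n)

  drivers <- data.frame(symbol = symbol, polarization = polarization,
                        weight = weight, stringsAsFactors = FALSE)
  drivers$evidence <- evidence
  if (anyDuplicated(drivers$symbol)) {
    merged <- lapply(split(seq_len(n), drivers$symbol), function(ix) {
      pol <- unique(drivers$polarization[ix])
      pol <- if (length(pol) > 1L) setdiff(pol, "unclassified") else pol
      if (length(pol) != 1L) {
        stop(sprintf("conflicting polarization for %s", drivers$symbol[ix[1L]]))
      }
      list(symbol = drivers$symbol[ix[1L]], polarization = pol,
           weight = sum(drivers$weight[ix]),
           evidence = sort(unique(unlist(drivers$evidence[ix]))))
    })
    drivers <- data.frame(
      symbol = vapply(merged, `[[`, "", "symbol"),
      polarization = vapply(merged, `[[`, "", "polarization"),
      weight = vapply(merged, `[[`, 0, "weight"),
      stringsAsFactors = FALSE)
    drivers$evidence <- lapply(merged, `[[`, "evidence")
  }
  drivers <- drivers[order(drivers$symbol), , drop = FALSE]
  rownames(drivers) <- NULL
  new_seed_set(drivers, provenance)
}

#' Load a driver-gene table
#'
#' TSV with header columns `symbol`, `polarization` (M1|M2|unclassified),
#' `evidence` (comma-joined tags) and optional `weight`. The alias table is
#' applied and duplicate symbols are merged (weights summed, evidence
#' unioned). The package ships a fixture encoding the validated 11-gene
#' M1/M2 marker panel (arginase, CLEC10A, CD206/MMR, VEGF, IL-1, IL-6, TNF,
#' YM1, FIZZ1, COX2, uPA).
#'
#' @param path Path to the TSV.
#' @param aliases Alias table; default the shipped fixture. Pass NULL to
#'   disable aliasing.
#' @return A `seed_set`.
#' @export
load_driver_table <- function(path, aliases = read_alias_table()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) == 0L) stop("empty driver table")
  stopifnot(all(c("symbol", "polarization") %in% names(tab)))
  seed_set(symbol = tab$symbol,
           polarization = tab$polarization,
           evidence = if ("evidence" %in% names(tab)) tab$evidence else "literature",
           weight = if ("weight" %in% names(tab)) tab$weight else 1,
           aliases = aliases,
           provenance = paste("loaded from", path))
}

#' Path to the shipped M1/M2 driver panel fixture
#' @return File path.
#' @export
driver_panel_path <- function() {
  system.file("extdata", "m1_m2_driver_panel.tsv", package = "polarnet")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d drivers (M1: %d, M2: %d, unclassified: %d)\n",
              nrow(x$drivers),
              sum(x$drivers$polarization == "M1"),
              sum(x$drivers$polarization == "M2"),
              sum(x$drivers$polarization == "unclassified")))
  invisible(x)
}

#' Map a seed set to a prior weight vector over network nodes
#'
#' Mapped drivers receive their weight at their node position; the vector is
#' then normalized to sum exactly 1 (the restart distribution Y of the
#' propagation iteration). Drivers absent from the network are reported in
#' `unmapped`, never silently dropped.
#'
#' @param seeds A `seed_set`.
#' @param ordering Node ordering (from [normalize_adjacency()]), or a
#'   `normalized_adjacency` object.
#' @return A `seed_vector`: list with `ordering`, `y` (named numeric summing
#'   to 1) and `unmapped` (character).
#' @export
build_seed_vector <- function(seeds, ordering) {
  if (inherits(ordering, "normalized_adjacency")) ordering <- ordering$ordering
  stopifnot(inherits(seeds, "seed_set"), length(ordering) >= 1L)
  y <- stats::setNames(numeric(length(ordering)), ordering)
  mapped <- seeds$drivers$symbol %in% ordering
  if (!any(mapped)) stop("no seeds on network: propagation undefined")
  y[seeds$drivers$symbol[mapped]] <- seeds$drivers$weight[mapped]
  y <- y / sum(y)
  structure(list(ordering = ordering, y = y,
                 unmapped = seeds$drivers$symbol[!mapped]),
            class = "seed_vector")
}

#' @export
print.seed_vector <- function(x, ...) {
  cat(sprintf("<seed_vector> %d mapped seeds over %d nodes (%d unmapped)\n",
              sum(x$y > 0), length(x$y), length(x$unmapped)))
  invisible(x)
}
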