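#' Load and validate a membrane composition table
#'
#' Reads a per-leaflet composition CSV with columns
#' `name,headgroup_class,tail_class,count_per_leaflet`.  Head-group classes
#' are PE, PG, PC, CL (phospholipids) or HOP (hopanoids); tail classes are
#' `sat` (contains a fully saturated acyl chain), `MU` (all chains
#' monounsaturated), `PU` (contains a polyunsaturated chain) or `none`
#' (hopanoids, which carry no glycerophospholipid acyl chains).
#'
#' Two tables ship with the package (see `system.file("extdata", ...)`):
#' `composition_wildtype.csv`, a 14-species hopanoid-containing model with
#' 100 molecules per leaflet (50 of them hopanoids), and
#' `composition_nohop.csv`, the hopanoid-free variant in which the twelve
#' phospholipid counts are doubled so the leaflet again totals 100.
#'
#' @param path Path to the CSV file.
#' @return A `membrane_composition` data.frame with attribute
#'   `leaflet_total` (sum of `count_per_leaflet`).
#' @examples
#' comp <- load_composition(system.file("extdata", "composition_wildtype.csv",
#'                                      package = "bilayertools"))
#' attr(comp, "leaflet_total")  # 100
#' @export
load_composition <- function(path) {
  if (!file.exists(path)) stop("composition file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "headgroup_class", "tail_class", "count_per_leaflet")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("composition file is missing column(s): ",
         paste(missing, collapse = ", "))
  as_membrane_composition(tab)
}

#' Construct a membrane composition from a data.frame
#'
#' @param tab data.frame with columns `name`, `headgroup_class`,
#'   `tail_class`, `count_per_leaflet`.
#' @return A validated `membrane_composition`.
#' @export
as_membrane_composition <- function(tab) {
  hg_levels <- c("PE", "PG", "PC", "CL", "HOP")
  tail_levels <- c("sat", "MU", "PU", "none")
  if (nrow(tab) == 0L) {
    warning("composition has no species; leaflet total is 0")
  }
  for (i in seq_len(nrow(tab))) {
    cnt <- tab$count_per_leaflet[i]
    if (!is.numeric(cnt) || !is.finite(cnt) || cnt < 0 || cnt != round(cnt))
      stop(sprintf("row %d (%s): count_per_leaflet must be a non-negative integer, got %s",
                   i, tab$name[i], format(cnt)))
    if (!tab$headgroup_class[i] %in% hg_levels)
      stop(sprintf("row %d (%s): unknown headgroup_class '%s'",
                   i, tab$name[i], tab$headgroup_class[i]))
    if (!tab$tail_class[i] %in% tail_levels)
      stop(sprintf("row %d (%s): unknown tail_class '%s'",
                   i, tab$name[i], tab$tail_class[i]))
    if (tab$headgroup_class[i] == "HOP" && tab$tail_class[i] != "none")
      stop(sprintf("row %d (%s): hopanoid species must have tail_class 'none'",
                   i, tab$name[i]))
  }
  tab$count_per_leaflet <- as.integer(tab$count_per_leaflet)
  structure(tab,
            leaflet_total = sum(tab$count_per_leaflet),
            class = c("membrane_composition", "data.frame"))
}

#' Number of molecules per leaflet
#' @param comp A `membrane_composition`.
#' @return Integer leaflet total.
#' @export
leaflet_total <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  attr(comp, "leaflet_total")
}

#' Grouped lipid-class counts and fractions
#'
#' Collapses a composition into the four lateral-mixing classes: HOP
#' (hopanoids, by head group), and sat/MU/PU phospholipids (by tail class).
#' Classes absent from the composition get a zero count.
#'
#' @param comp A `membrane_composition`.
#' @return data.frame with columns `class`, `count`, `fraction`.
#' @export
class_fractions <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  cls <- ifelse(comp$headgroup_class == "HOP", "HOP", comp$tail_class)
  lev <- c("HOP", "sat", "MU", "PU")
  counts <- vapply(lev, function(l) sum(comp$count_per_leaflet[cls == l]), 0)
  total <- sum(counts)
  data.frame(class = lev, count = as.integer(counts),
             fraction = if (total > 0) counts / total else rep(NA_real_, 4L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat(sprintf("<membrane_composition> %d species, %d molecules per leaflet\n",
              nrow(x), attr(x, "leaflet_total")))
  print.data.frame(x, ...)
  invisible(x)
}
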