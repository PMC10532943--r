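#' Published colon immune cell subtype sample sizes
#'
#' Sample sizes of the 25 immune cell subtypes of the Gut Cell Atlas
#' normal-colon scRNA-seq reference (James KR et al., 41,650 cells in
#' total). These proportions define the `"colon-immune"` imbalance profile
#' of the synthetic-data generator: the largest class (IgA plasma B cells,
#' 12,522 cells) outnumbers the smallest (lymphoid dendritic cells, 10
#' cells) by a factor of 1252.
#'
#' @return a named integer vector of length 25 (subtype -> cell count).
#' @examples
#' sum(colon_immune_class_sizes())      # 41650
#' @export
colon_immune_class_sizes <- function() {
  c(
    "Activated CD4 T"    = 1531L,
    "B cell (cycling)"   = 15L,
    "B cell (IgA Plasma)" = 12522L,
    "B cell (IgG Plasma)" = 342L,
    "B cell (memory)"    = 4508L,
    "CD8 T"              = 3145L,
    "cDC1"               = 38L,
    "cDC2"               = 107L,
    "cycling DCs"        = 47L,
    "cycling gd T"       = 25L,
    "Follicular B cell"  = 2582L,
    "gd T"               = 548L,
    "ILC"                = 832L,
    "Lymphoid DC"        = 10L,
    "LYVE1 Macrophage"   = 91L,
    "Macrophage"         = 268L,
    "Mast"               = 1151L,
    "Monocyte"           = 98L,
    "NK"                 = 452L,
    "pDC"                = 13L,
    "Tcm"                = 3042L,
    "Tfh"                = 1786L,
    "Th1"                = 2833L,
    "Th17"               = 3432L,
    "Treg"               = 2232L
  )
}

#' Rescale an imbalance profile to a target total
#'
#' Rescales a vector of class sizes (by default the published colon immune
#' profile) to approximately `total_cells` cells, preserving proportions and
#' flooring every class at `min_size` cells so that downstream oversampling
#' always has at least one same-class neighbor.
#'
#' @param total_cells target total cell count.
#' @param sizes reference class sizes (named); default
#'   [colon_immune_class_sizes()].
#' @param min_size minimum cells per class (default 2).
#' @return named integer vector of rescaled class sizes.
#' @export
scale_class_sizes <- function(total_cells, sizes = colon_immune_class_sizes(),
                              min_size = 2L) {
  total_cells <- check_count(total_cells, "total_cells", min = length(sizes) * min_size)
  out <- pmax(min_size, as.integer(round(sizes / sum(sizes) * total_cells)))
  names(out) <- names(sizes)
  out
}
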