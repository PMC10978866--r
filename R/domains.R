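#' Domain map over a protein
#'
#' A named set of 1-based, fully closed intervals used for regional
#' aggregation of enrichment scores. Regions may leave gaps; positions not
#' covered by any region fall into an implicit `"background"` region for
#' effect assignment.
#'
#' @param region Character vector of region names (unique).
#' @param start,end Integer vectors of 1-based closed interval bounds,
#'   `start <= end`.
#' @return A data frame of class `domain_map` with columns `region`,
#'   `start`, `end`.
#' @export
domain_map <- function(region, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(region) == length(start), length(start) == length(end))
  if (anyDuplicated(region)) {
    stop("duplicate region names", call. = FALSE)
  }
  if (any(start < 1L) || any(end < start)) {
    stop("regions must satisfy 1 <= start <= end", call. = FALSE)
  }
  structure(
    data.frame(region = as.character(region), start = start, end = end,
               stringsAsFactors = FALSE),
    class = c("domain_map", "data.frame")
  )
}

#' Default EGFR domain map
#'
#' Tiling of the 1210-residue EGFR protein into its canonical regions,
#' using the coordinates of the screened construct: extracellular domains
#' I-IV (with the cysteine-rich dimerization domains II, 189-333, and IV,
#' 504-644), the transmembrane helix (645-668), the juxtamembrane segment,
#' the kinase domain and the C-terminal tail (979-1210). Editable: build
#' your own with [domain_map()].
#'
#' @return A `domain_map` data frame.
#' @export
egfr_domains <- function() {
  domain_map(
    region = c("domain_I", "domain_II", "domain_III", "domain_IV",
               "TM", "JM", "kinase", "C_terminal"),
    start = c(1L, 189L, 334L, 504L, 645L, 669L, 712L, 979L),
    end = c(188L, 333L, 503L, 644L, 668L, 711L, 978L, 1210L)
  )
}

# Region name for each protein position; first matching region in map
# order wins, uncovered positions get "background".
region_of_position <- function(aa_pos, map) {
  stopifnot(inherits(map, "domain_map"))
  out <- rep("background", length(aa_pos))
  for (i in rev(seq_len(nrow(map)))) {
    hit <- aa_pos >= map$start[i] & aa_pos <= map$end[i]
    out[hit] <- map$region[i]
  }
  out
}
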