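#' The 90-region AAL cortical/subcortical atlas table
#'
#' Automated-anatomical-labeling parcellation of the cerebrum into 90
#' regions, 45 per hemisphere (odd indices left, even right), shipped as a
#' packaged lookup. The \code{lobe} column carries a coarse anatomical tag
#' (frontal, limbic, occipital, parietal, subcortical, temporal) used to
#' annotate connections absent from the consensus taxonomy.
#'
#' @return data.frame with columns \code{index}, \code{name},
#'   \code{abbrev}, \code{hemisphere}, \code{lobe}.
#' @export
region_atlas <- function() {
  path <- system.file("extdata", "aal90_atlas.csv", package = "connclass",
                      mustWork = TRUE)
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(atlas) == 90, sum(atlas$hemisphere == "L") == 45,
            sum(atlas$hemisphere == "R") == 45,
            !anyDuplicated(paste(atlas$name, atlas$hemisphere)))
  atlas
}

#' Consensus-connection taxonomy lookup
#'
#' Network/subnetwork labels (cortical-limbic and its frontal-, parietal-
#' and temporal-limbic subdivisions, plus occipital-temporal) for the 33
#' connections reported as discriminating in the motivating depression
#' study, keyed by region-name pair.
#'
#' @return data.frame with columns \code{roi_a}, \code{hemi_a},
#'   \code{roi_b}, \code{hemi_b}, \code{network}, \code{subnetwork},
#'   \code{mean_p}.
#' @export
consensus_taxonomy <- function() {
  path <- system.file("extdata", "consensus_annotations.csv",
                      package = "connclass", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Map atlas (name, hemisphere) -> region index.
.atlas_index <- function(atlas, name, hemi) {
  idx <- atlas$index[match(paste(name, hemi), paste(atlas$name, atlas$hemisphere))]
  if (anyNA(idx))
    stop("unknown region(s): ",
         paste(paste(name, hemi)[is.na(idx)], collapse = ", "))
  idx
}

#' Annotate region pairs with network/subnetwork tags
#'
#' Pairs present in the packaged consensus taxonomy receive its network and
#' subnetwork labels; any other pair receives a lobe-pair tag derived from
#' the atlas (e.g. \code{"frontal-limbic"}).
#'
#' @param i,j vectors of 1-based region indices.
#' @param atlas atlas table from \code{\link{region_atlas}}.
#' @return data.frame with columns \code{network}, \code{subnetwork}.
#' @export
annotate_edges <- function(i, j, atlas = region_atlas()) {
  stopifnot(length(i) == length(j))
  tax <- consensus_taxonomy()
  ta <- .atlas_index(atlas, tax$roi_a, tax$hemi_a)
  tb <- .atlas_index(atlas, tax$roi_b, tax$hemi_b)
  key <- paste(pmin(ta, tb), pmax(ta, tb))
  qkey <- paste(pmin(i, j), pmax(i, j))
  hit <- match(qkey, key)
  lobes <- function(r) atlas$lobe[match(r, atlas$index)]
  fallback <- paste(pmin(lobes(i), lobes(j)), pmax(lobes(i), lobes(j)),
                    sep = "-")
  data.frame(
    network = ifelse(is.na(hit), fallback, tax$network[hit]),
    subnetwork = ifelse(is.na(hit), fallback, tax$subnetwork[hit]),
    stringsAsFactors = FALSE)
}

#' Human-readable edge labels
#'
#' @param i,j vectors of 1-based region indices.
#' @param atlas atlas table.
#' @return character vector like \code{"ORBmid.L--HIP.L"}.
#' @export
edge_labels <- function(i, j, atlas = region_atlas()) {
  lab <- function(r) paste0(atlas$abbrev[match(r, atlas$index)], ".",
                            atlas$hemisphere[match(r, atlas$index)])
  paste0(lab(pmin(i, j)), "--", lab(pmax(i, j)))
}
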