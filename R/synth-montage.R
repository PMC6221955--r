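# 64-channel 10-10 montage and right centro-parietal/parieto-occipital
# electrode clusters.
#
# Channel positions are idealized: each label is mapped to 2-D layout
# coordinates (anterior-posterior and lateral angles in 18-degree 10-10
# steps) and projected onto the unit sphere with the azimuthal-equidistant
# inverse. Nothing downstream depends on geometry beyond cluster membership,
# which is a named config (inst/extdata/clusters.csv) that users can edit.

# standard 64-channel active-electrode cap labels (10-10 subset)
MONTAGE_64 <- c(
  "Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9",
  "CP5", "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8",
  "TP10", "CP6", "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2", "F4",
  "F8", "Fp2", "AF7", "AF3", "AFz", "F1", "F5", "FT7", "FC3", "C1",
  "C5", "TP7", "CP3", "P1", "P5", "PO7", "PO3", "POz", "PO4", "PO8",
  "P6", "P2", "CPz", "CP4", "TP8", "C6", "C2", "FC4", "FT8", "F6",
  "AF8", "AF4", "F2", "Iz"
)

# anterior-posterior angle (deg from vertex, + = front) per label prefix row
ROW_ANGLE <- c(Fp = 72, AF = 54, F = 36, FT = 18, FC = 18, C = 0,
               T = 0, TP = -18, CP = -18, P = -36, PO = -54, O = -72,
               I = -90)

label_layout <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(p?)([0-9]+|z)$", label))[[1]]
  # Fp1/Fp2 match as prefix "F" + "p"; rejoin
  prefix <- paste0(m[2], m[3])
  suffix <- m[4]
  if (!prefix %in% names(ROW_ANGLE)) prefix <- m[2]
  ap <- ROW_ANGLE[[prefix]]
  if (suffix == "z") {
    lat <- 0
  } else {
    k <- as.integer(suffix)
    # odd numbers left, even right; 1,2 -> 18deg; 3,4 -> 36deg; 7,8 -> 72deg
    step <- ceiling(k / 2) * 18
    # temporal rows label 7/8 at 72 deg but 9/10 (ear-level) at 90 deg
    if (k >= 9) step <- 90
    lat <- ifelse(k %% 2 == 1, -step, step)
  }
  c(ap = ap, lat = lat)
}

#' Default 64-channel montage with analysis clusters
#'
#' Builds the 64-channel 10-10 montage with idealized unit-sphere positions
#' and the four right-hemisphere electrode clusters (C1 right centro-parietal,
#' C2 right parietal, C4 right parieto-occipital, C5 right occipital) used
#' for feature pooling. Cluster memberships are read from a plain CSV config.
#'
#' @param cluster_file path to a two-column CSV (cluster, channel); defaults
#'   to the config shipped with the package.
#' @return A `montage` object: `$channels` (64 labels), `$positions`
#'   (64 x 3 matrix on the unit sphere), `$clusters` (named list of channel
#'   vectors).
#' @export
default_montage <- function(cluster_file = system.file("extdata",
                                                       "clusters.csv",
                                                       package = "emobio")) {
  pos <- t(vapply(MONTAGE_64, function(lb) {
    ang <- label_layout(lb)
    incl <- sqrt(ang[["ap"]]^2 + ang[["lat"]]^2) * pi / 180
    az <- atan2(ang[["lat"]], ang[["ap"]])
    c(sin(incl) * sin(az), sin(incl) * cos(az), cos(incl))
  }, numeric(3)))
  colnames(pos) <- c("x", "y", "z")  # x: left->right, y: back->front, z: up
  cl <- utils::read.csv(cluster_file, stringsAsFactors = FALSE)
  clusters <- split(cl$channel, cl$cluster)
  montage <- structure(list(channels = MONTAGE_64, positions = pos,
                            clusters = clusters), class = "montage")
  validate_montage(montage)
  montage
}

validate_montage <- function(m) {
  stopifnot(length(m$channels) == 64L, !anyDuplicated(m$channels))
  all_cl <- unlist(m$clusters, use.names = FALSE)
  if (anyDuplicated(all_cl))
    stop("montage clusters must be pairwise disjoint")
  missing <- setdiff(all_cl, m$channels)
  if (length(missing))
    stop("cluster channels not in montage: ", paste(missing, collapse = ", "))
  invisible(m)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels; clusters: %s\n", length(x$channels),
              paste(sprintf("%s(%d)", names(x$clusters),
                            lengths(x$clusters)), collapse = ", ")))
  invisible(x)
}
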