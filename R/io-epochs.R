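# EpochSet persistence: raw float64 tensor + JSON sidecar with dims,
# labels, window and rejection mask.

#' Write / read an epoch set
#'
#' The tensor is written as little-endian float64 in trial-major order next
#' to a JSON sidecar (`<base>.json`) holding dimensions, channel labels,
#' window, sampling rate, per-trial conditions and the rejection mask.
#'
#' @param ep an `epoch_set`
#' @param base output path without extension
#' @export
write_epochs <- function(ep, base) {
  con <- file(paste0(base, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(ep$data), con, size = 8, endian = "little")
  side <- list(dim = dim(ep$data), channels = dimnames(ep$data)[[2]],
               window = ep$window, rate_hz = ep$rate_hz,
               condition = ep$condition, rejected = ep$rejected)
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(base) {
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  con <- file(paste0(base, ".bin"), "rb")
  on.exit(close(con))
  n <- prod(side$dim)
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  data <- array(x, dim = side$dim,
                dimnames = list(NULL, side$channels, NULL))
  structure(list(data = data, window = side$window, rate_hz = side$rate_hz,
                 condition = side$condition, rejected = side$rejected,
                 events = NULL, montage = NULL),
            class = "epoch_set")
}
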