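# WiSARD weightless neural network with bleaching, on thermometer-encoded
# feature vectors.
#
# Each class owns one discriminator: a set of RAM nodes, one per tuple of
# the (seeded, fixed) random permutation of input bits. Training writes the
# observed address of every tuple into that node's counter table;
# classification counts, per class, the tuples whose counter at the observed
# address reaches the bleaching threshold b, raising b from 1 until the
# argmax is unique. Counter tables are dense (2^n_tuple rows), which keeps
# the unseen-address-reads-zero contract trivially.

#' Fit a thermometer encoder
#'
#' Per-feature min/max are taken from the training rows only. A value `v`
#' maps to `floor(bits * clip((v - min)/(max - min), 0, 1))` leading ones
#' followed by zeros; values outside the training range saturate. A
#' constant feature (min == max) encodes to all zeros, with a warning.
#'
#' @param train_features numeric matrix (rows = examples)
#' @param bits bits per feature (>= 2, default 16)
#' @return an `encoder`
#' @export
fit_encoder <- function(train_features, bits = 16L) {
  stopifnot(is.matrix(train_features), nrow(train_features) >= 2, bits >= 2)
  mins <- apply(train_features, 2, min)
  maxs <- apply(train_features, 2, max)
  if (any(maxs == mins)) {
    warning(sprintf("%d constant feature(s): encoded as all-zero",
                    sum(maxs == mins)))
  }
  structure(list(bits = as.integer(bits), mins = mins, maxs = maxs),
            class = "encoder")
}

#' Thermometer-encode a feature matrix
#'
#' @param enc an `encoder`
#' @param features numeric matrix with the same columns the encoder was
#'   fitted on
#' @return binary 0/1 matrix with `bits * ncol(features)` columns
#' @export
encode <- function(enc, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  stopifnot(ncol(features) == length(enc$mins))
  bits <- enc$bits
  rng <- enc$maxs - enc$mins
  out <- matrix(0L, nrow(features), ncol(features) * bits)
  for (j in seq_len(ncol(features))) {
    frac <- if (rng[j] == 0) rep(0, nrow(features)) else
      pmin(1, pmax(0, (features[, j] - enc$mins[j]) / rng[j]))
    nset <- floor(bits * frac)
    cols <- (j - 1) * bits + seq_len(bits)
    for (i in seq_len(nrow(features))) {
      if (nset[i] > 0) out[i, cols[seq_len(nset[i])]] <- 1L
    }
  }
  out
}

#' Create an untrained WiSARD model
#'
#' @param n_bits total input bits (e.g. `bits * n_features`)
#' @param classes class labels (two or more)
#' @param n_tuple address tuple size (default 4)
#' @param seed seed fixing the bit-permutation mapping
#' @return a `wisard` model
#' @export
wisard_model <- function(n_bits, classes, n_tuple = 4L, seed = 1L) {
  stopifnot(n_bits >= 1, length(classes) >= 2, n_tuple >= 1, n_tuple <= 24)
  set.seed(seed)
  pad <- (n_tuple - n_bits %% n_tuple) %% n_tuple
  mapping <- sample(n_bits + pad)  # padded bits are always-zero inputs
  n_nodes <- (n_bits + pad) / n_tuple
  tables <- lapply(classes, function(cl) {
    matrix(0L, nrow = 2^n_tuple, ncol = n_nodes)
  })
  names(tables) <- as.character(classes)
  structure(list(n_bits = as.integer(n_bits), pad = as.integer(pad),
                 n_tuple = as.integer(n_tuple), mapping = mapping,
                 classes = as.character(classes), tables = tables,
                 n_nodes = n_nodes, trained = FALSE, seed = as.integer(seed)),
            class = "wisard")
}

# addresses (1-based rows of the counter tables) of one encoded vector
wisard_addresses <- function(model, x) {
  xp <- c(as.integer(x), rep(0L, model$pad))[model$mapping]
  tup <- matrix(xp, nrow = model$n_tuple)
  as.integer(2L^(seq_len(model$n_tuple) - 1L) %*% tup) + 1L
}

#' Train a WiSARD model
#'
#' For every example, each tuple of its class's discriminator increments the
#' counter at the tuple's observed address by one.
#'
#' @param model a `wisard`
#' @param encoded binary matrix (rows = examples, `n_bits` columns)
#' @param labels class label per row
#' @return the updated model
#' @export
wisard_train <- function(model, encoded, labels) {
  if (is.null(dim(encoded))) encoded <- matrix(encoded, nrow = 1)
  if (ncol(encoded) != model$n_bits) {
    stop("encoded width ", ncol(encoded), " != model n_bits ", model$n_bits)
  }
  stopifnot(length(labels) == nrow(encoded),
            all(as.character(labels) %in% model$classes))
  node <- seq_len(model$n_nodes)
  for (i in seq_len(nrow(encoded))) {
    addr <- wisard_addresses(model, encoded[i, ])
    cl <- as.character(labels[i])
    idx <- cbind(addr, node)
    model$tables[[cl]][idx] <- model$tables[[cl]][idx] + 1L
  }
  model$trained <- TRUE
  model
}

# per-class counters at the input's addresses
wisard_counters <- function(model, x) {
  addr <- wisard_addresses(model, x)
  idx <- cbind(addr, seq_len(model$n_nodes))
  vapply(model$tables, function(tab) tab[idx], integer(model$n_nodes))
}

#' Classify with bleaching
#'
#' Responses at bleaching threshold `b` are, per class, the number of RAM
#' nodes whose counter at the observed address is at least `b`. Starting at
#' `b = 1`, the threshold is raised while the best response is tied; if the
#' tie persists until all responses reach zero, the class with the larger
#' raw (`b = 1`) response wins, then lexicographic label order.
#'
#' @param model a trained `wisard`
#' @param encoded one encoded vector (or single-row matrix)
#' @return list(label, responses at the deciding threshold, bleach level)
#' @export
wisard_classify <- function(model, encoded) {
  if (!model$trained) stop("model is untrained")
  x <- if (is.matrix(encoded)) encoded[1, ] else encoded
  cnt <- wisard_counters(model, x)  # n_nodes x n_classes
  cnt <- matrix(cnt, ncol = length(model$classes),
                dimnames = list(NULL, model$classes))
  b <- 1L
  raw <- colSums(cnt >= 1L)
  repeat {
    resp <- colSums(cnt >= b)
    top <- which(resp == max(resp))
    if (length(top) == 1L) {
      return(list(label = model$classes[top], responses = resp,
                  bleach = b))
    }
    if (all(resp == 0L)) {
      tied <- model$classes[raw == max(raw)]
      return(list(label = sort(tied)[1], responses = resp, bleach = b))
    }
    b <- b + 1L
  }
}

#' Predict labels for a matrix of encoded vectors
#'
#' @param model a trained `wisard`
#' @param encoded binary matrix
#' @return character vector of labels
#' @export
wisard_predict <- function(model, encoded) {
  if (is.null(dim(encoded))) encoded <- matrix(encoded, nrow = 1)
  vapply(seq_len(nrow(encoded)), function(i) {
    wisard_classify(model, encoded[i, ])$label
  }, character(1))
}

#' Serialize / restore a WiSARD model as JSON
#'
#' Counters are written sparsely (address, node, count triples per class).
#'
#' @param model a `wisard`
#' @param path file path
#' @export
write_wisard <- function(model, path) {
  sparse <- lapply(model$tables, function(tab) {
    nz <- which(tab != 0, arr.ind = TRUE)
    data.frame(address = nz[, 1], node = nz[, 2], count = tab[nz])
  })
  obj <- list(n_bits = model$n_bits, pad = model$pad,
              n_tuple = model$n_tuple, mapping = model$mapping,
              classes = model$classes, counters = sparse,
              trained = model$trained, seed = model$seed)
  if (!is.null(model$encoder)) {
    obj$encoder <- unclass(model$encoder)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wisard
#' @export
read_wisard <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- wisard_model(obj$n_bits, obj$classes, obj$n_tuple, obj$seed)
  model$mapping <- as.integer(obj$mapping)
  for (cl in obj$classes) {
    sp <- obj$counters[[cl]]
    if (length(sp) && nrow(sp)) {
      model$tables[[cl]][cbind(sp$address, sp$node)] <- as.integer(sp$count)
    }
  }
  model$trained <- isTRUE(obj$trained)
  if (!is.null(obj$encoder)) {
    model$encoder <- structure(list(bits = as.integer(obj$encoder$bits),
                                    mins = obj$encoder$mins,
                                    maxs = obj$encoder$maxs),
                               class = "encoder")
  }
  model
}

#' @export
print.wisard <- function(x, ...) {
  cat(sprintf("<wisard> %d bits (+%d pad), %d nodes of %d-bit tuples, classes: %s%s\n",
              x$n_bits, x$pad, x$n_nodes, x$n_tuple,
              paste(x$classes, collapse = "/"),
              if (x$trained) "" else " (untrained)"))
  invisible(x)
}
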