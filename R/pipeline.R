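# Subject-level feature tables and the repeated-holdout evaluation harness.
#
# Feature vectors have 160 entries: 8 features x 5 bands x 4 right
# centro-parietal/parieto-occipital clusters (C1, C2, C4, C5), each entry a
# mean over imagery trials and cluster channels. Feature selection ranks
# training-fold columns by absolute Welch t and never sees test rows.

CLUSTER_KEYS <- c("C1", "C2", "C4", "C5")

#' Canonical feature keys
#'
#' The fixed column order of a feature table:
#' `feature__band__cluster` over 8 features x 5 bands x 4 clusters = 160.
#'
#' @param clusters cluster names (default C1, C2, C4, C5)
#' @return character vector of keys
#' @export
feature_keys <- function(clusters = CLUSTER_KEYS) {
  as.vector(outer(as.vector(outer(ALL_FEATURES, names(eeg_bands()),
                                  paste, sep = "__")),
                  clusters, paste, sep = "__"))
}

#' Average windowed features over trials and cluster channels
#'
#' For one subject: per (feature, band, cluster), the mean of the chosen
#' window's values over all non-rejected trials and the cluster's channels,
#' skipping NA sentinels (counts are reported via message when any are
#' skipped).
#'
#' @param wf a (normalized) `windowed_features` table
#' @param montage montage defining the clusters
#' @param window `"emotion"` or `"neutral"`
#' @return named numeric vector over [feature_keys()]
#' @export
cluster_average <- function(wf, montage, window = c("emotion", "neutral")) {
  window <- match.arg(window)
  w <- window  # avoid NSE capture of the argument name
  cl_map <- data.table::rbindlist(lapply(names(montage$clusters), function(cl) {
    data.table::data.table(cluster = cl, channel = montage$clusters[[cl]])
  }))
  sub <- wf[wf$window == w]
  sub <- merge(sub, cl_map, by = "channel")
  n_na <- sum(is.na(sub$value))
  if (n_na > 0) {
    message(sprintf("cluster_average: skipping %d undefined feature value(s)",
                    n_na))
  }
  agg <- sub[, list(value = mean(value, na.rm = TRUE)),
             by = list(feature, band, cluster)]
  keys <- feature_keys(sort(names(montage$clusters)))
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  out[paste(agg$feature, agg$band, agg$cluster, sep = "__")] <- agg$value
  out
}

#' Assemble a subject-by-feature table
#'
#' @param rows list of named feature vectors (one per subject), all over the
#'   same keys
#' @param group group label per subject (`"asd"` / `"td"`)
#' @param subjects subject identifiers
#' @param covariates optional data.frame of per-subject covariates (FSIQ...)
#' @return a `feature_table`: `$x` (subjects x features matrix), `$group`,
#'   `$subjects`, `$covariates`
#' @export
feature_table <- function(rows, group, subjects = NULL, covariates = NULL) {
  x <- do.call(rbind, rows)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_len(nrow(x)))
  rownames(x) <- subjects
  stopifnot(length(group) == nrow(x), !anyDuplicated(subjects))
  structure(list(x = x, group = as.character(group), subjects = subjects,
                 covariates = covariates), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s:%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a cohort and build its feature tables
#'
#' End-to-end convenience: per subject, simulate the recording, band-pass
#' (1 Hz to 100 Hz or 90% of Nyquist, whichever is lower), notch (when 50 Hz
#' is in band), average-reference, epoch on the instruction onset, reject
#' bad epochs, extract and normalize windowed features, and average over
#' trials and cluster channels. Recordings are discarded as soon as each
#' subject's features are computed, so memory stays flat in cohort size.
#'
#' @param spec a `cohort_spec`
#' @param schedule_fun function(seed) -> `trial_schedule`
#' @param montage montage
#' @param verbose print per-subject progress
#' @return list with `feature_table`s `$emotion` and `$neutral`
#' @export
cohort_feature_table <- function(spec, schedule_fun = make_imagery_schedule,
                                 montage = default_montage(),
                                 verbose = FALSE) {
  groups <- rep(c("asd", "td"), each = spec$n_per_group)
  cluster_channels <- unlist(montage$clusters, use.names = FALSE)
  windows <- imagery_feature_windows()
  emo <- vector("list", length(groups))
  neu <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sd_i <- subject_seed(spec$seed, i)
    sched <- schedule_fun(sd_i + 1L)
    rec <- simulate_subject(spec, groups[i], sched, sd_i, montage)
    rec <- bandpass(rec, 1, min(100, 0.45 * rec$rate_hz))
    if (rec$rate_hz > 2 * 52.5 / 0.9) rec <- notch(rec)
    rec <- rereference_average(rec)
    ep <- epoch(rec, "instruction", -500, sum(sched$segments))
    ep <- reject_bad_epochs(ep)
    wf <- extract_all(ep, montage, windows = windows,
                      channels = cluster_channels)
    wf <- normalize_features(wf)
    emo[[i]] <- cluster_average(wf, montage, "emotion")
    neu[[i]] <- cluster_average(wf, montage, "neutral")
    if (verbose) message(sprintf("subject %d/%d done", i, length(groups)))
  }
  list(emotion = feature_table(emo, groups),
       neutral = feature_table(neu, groups))
}

#' Rank features by absolute Welch t
#'
#' Two-sample (unequal-variance) t statistics per column, computed on the
#' given (training) table only, ordered by decreasing absolute t; ties
#' break by fixed column order.
#'
#' @param train a `feature_table` with at least 2 subjects per group
#' @param pooled use the pooled-variance statistic instead of Welch
#' @return data.frame(key, t) in rank order
#' @export
rank_features <- function(train, pooled = FALSE) {
  g <- unique(train$group)
  stopifnot(length(g) == 2)
  a <- train$x[train$group == g[1], , drop = FALSE]
  b <- train$x[train$group == g[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("each group needs at least 2 training subjects")
  }
  tval <- welch_t(a, b, pooled = pooled)
  ord <- order(-abs(tval))  # stable: ties keep column order
  data.frame(key = colnames(train$x)[ord], t = tval[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# vectorized column-wise two-sample t (Welch or pooled)
welch_t <- function(a, b, pooled = FALSE) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  if (pooled) {
    sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    (ma - mb) / sqrt(sp * (1 / na + 1 / nb))
  } else {
    (ma - mb) / sqrt(va / na + vb / nb)
  }
}

#' Stratified random holdout split
#'
#' Per group, `round(train_frac * n_group)` subjects go to training, the
#' rest to testing; the union is everyone and the sets are disjoint.
#'
#' @param table a `feature_table`
#' @param train_frac training fraction in (0, 1) (default 0.8)
#' @param seed split seed
#' @return list(train, test) of row indices
#' @export
holdout_split <- function(table, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  set.seed(seed)
  train <- integer()
  for (g in unique(table$group)) {
    rows <- which(table$group == g)
    if (length(rows) < 2) stop("group ", g, " has fewer than 2 subjects")
    n_tr <- round(train_frac * length(rows))
    n_tr <- min(max(n_tr, 1L), length(rows) - 1L)
    train <- c(train, sample(rows, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(seq_len(nrow(table$x)),
                                                train)))
}

# L2-regularized squared-hinge linear SVM (primal, L-BFGS). A
# maximum-margin linear separator; `cost` plays the role of C.
svm_linear_fit <- function(x, y, cost = 1) {
  yy <- ifelse(y == sort(unique(y))[1], 1, -1)
  pos <- sort(unique(y))[1]
  d <- ncol(x)
  obj <- function(par) {
    w <- par[1:d]; b <- par[d + 1]
    m <- pmax(0, 1 - yy * (drop(x %*% w) + b))
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(par) {
    w <- par[1:d]; b <- par[d + 1]
    m <- pmax(0, 1 - yy * (drop(x %*% w) + b))
    gw <- w - 2 * cost * drop(t(x) %*% (yy * m))
    gb <- -2 * cost * sum(yy * m)
    c(gw, gb)
  }
  fit <- optim(rep(0, d + 1), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 200))
  list(w = fit$par[1:d], b = fit$par[d + 1], positive = pos,
       negative = setdiff(sort(unique(y)), pos))
}

svm_linear_predict <- function(fit, x) {
  s <- drop(x %*% fit$w) + fit$b
  ifelse(s >= 0, fit$positive, fit$negative)
}

#' Binary classification metrics
#'
#' Standard definitions with the clinical group ("asd") as positive class.
#' Ratios with a zero denominator are NA sentinels, not 0.
#'
#' @param confusion named counts `c(tp, tn, fp, fn)`
#' @return list(accuracy, specificity, sensitivity, precision, f1)
#' @export
binary_metrics <- function(confusion) {
  tp <- confusion[["tp"]]; tn <- confusion[["tn"]]
  fp <- confusion[["fp"]]; fn <- confusion[["fn"]]
  stopifnot(all(c(tp, tn, fp, fn) >= 0), tp + tn + fp + fn > 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       specificity = ratio(tn, tn + fp),
       sensitivity = sens, precision = prec, f1 = f1)
}

confusion_counts <- function(truth, pred, positive = "asd") {
  c(tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive))
}

fit_and_score <- function(classifier, train_x, train_y, test_x, test_y,
                          bits, n_tuple, model_seed, cost,
                          standardize = TRUE) {
  if (classifier == "svm_linear") {
    if (standardize) {
      mu <- colMeans(train_x)
      s <- apply(train_x, 2, sd)
      s[s == 0] <- 1
      train_x <- sweep(sweep(train_x, 2, mu), 2, s, "/")
      test_x <- sweep(sweep(test_x, 2, mu), 2, s, "/")
    }
    fit <- svm_linear_fit(train_x, train_y, cost = cost)
    pred <- svm_linear_predict(fit, test_x)
  } else {
    enc <- suppressWarnings(fit_encoder(train_x, bits))
    model <- wisard_model(ncol(train_x) * bits, sort(unique(train_y)),
                          n_tuple, seed = model_seed)
    model <- wisard_train(model, encode(enc, train_x), train_y)
    pred <- wisard_predict(model, encode(enc, test_x))
  }
  pred
}

#' Repeated stratified holdout evaluation
#'
#' Per repetition: stratified 80/20 split, Welch-t feature ranking on the
#' training rows, then for every feature count `k` the top-k columns are
#' selected and both classifiers are fitted on the training rows and scored
#' on the held-out rows. Feature selection, standardization and encoder
#' fitting never see test rows. When a `neutral` table is supplied the whole
#' procedure is repeated on it with the same splits and a paired
#' per-repetition t-test contrasts emotion against neutral accuracy at each
#' k (FDR-adjusted across k).
#'
#' @param table emotion-window `feature_table`
#' @param classifiers subset of `c("svm_linear", "wisard")`
#' @param k_grid feature counts (default `seq(5, 160, by = 5)`)
#' @param reps repetitions (default 50)
#' @param seed master seed; per-repetition seeds are derived from it
#' @param neutral optional neutral-window `feature_table` (same subjects)
#' @param metrics_k feature count for the headline metric table (default 15;
#'   set 25 to match the alternative reading of the figure caption)
#' @param bits,n_tuple WiSARD encoder resolution and tuple size
#' @param cost SVM regularization constant
#' @param standardize z-score features with training-fold statistics before
#'   the SVM fit (default TRUE; the WiSARD thermometer encoder is scale-free)
#' @param permute_labels chance-level calibration mode: group labels are
#'   freshly permuted at every repetition (a proper permutation null; a
#'   single fixed permutation would retain exploitable sampling
#'   correlations)
#' @return an `evaluation_report`
#' @export
evaluate <- function(table, classifiers = c("svm_linear", "wisard"),
                     k_grid = seq(5, 160, by = 5), reps = 50, seed = 1L,
                     neutral = NULL, metrics_k = 15L, bits = 16L,
                     n_tuple = 4L, cost = 1, standardize = TRUE,
                     permute_labels = FALSE) {
  stopifnot(reps >= 1, all(k_grid >= 1))
  if (any(k_grid > ncol(table$x))) {
    stop("k_grid exceeds the number of features (", ncol(table$x), ")")
  }
  classifiers <- match.arg(classifiers, c("svm_linear", "wisard"),
                           several.ok = TRUE)
  runs <- list(emotion = table)
  if (!is.null(neutral)) runs$neutral <- neutral
  set.seed(seed)
  rep_seeds <- sample.int(2^30, reps)
  acc <- list(); sel <- list(); conf <- list()
  ai <- 0L
  for (r in seq_len(reps)) {
    split <- holdout_split(table, 0.8, rep_seeds[r])
    for (run in names(runs)) {
      tab <- runs[[run]]
      if (permute_labels) {
        set.seed(rep_seeds[r] + 1L)
        tab$group <- sample(tab$group)
      }
      train <- subset_table(tab, split$train)
      test <- subset_table(tab, split$test)
      ranking <- rank_features(train)
      s <- data.table::data.table(run = run, rep = r,
                                  rank = seq_len(metrics_k))
      s$key <- ranking$key[seq_len(metrics_k)]  # "key" is reserved in data.table()
      sel[[length(sel) + 1L]] <- s
      for (k in k_grid) {
        keys <- ranking$key[seq_len(k)]
        for (clf in classifiers) {
          pred <- fit_and_score(clf,
                                train$x[, keys, drop = FALSE], train$group,
                                test$x[, keys, drop = FALSE], test$group,
                                bits, n_tuple,
                                model_seed = rep_seeds[r] %% 100000L + k,
                                cost = cost, standardize = standardize)
          cc <- confusion_counts(test$group, pred)
          ai <- ai + 1L
          acc[[ai]] <- data.table::data.table(
            run = run, classifier = clf, k = k, rep = r,
            accuracy = (cc[["tp"]] + cc[["tn"]]) / sum(cc))
          if (k == metrics_k) {
            conf[[length(conf) + 1L]] <- data.table::data.table(
              run = run, classifier = clf, rep = r, t(cc))
          }
        }
      }
    }
  }
  acc <- data.table::rbindlist(acc)
  conf <- data.table::rbindlist(conf)
  sel <- data.table::rbindlist(sel)
  report <- list(accuracy = acc, confusions = conf, selections = sel,
                 metrics = summarize_metrics(conf),
                 contrast = if (!is.null(neutral))
                   accuracy_contrast(acc, k_grid, classifiers) else NULL,
                 params = list(k_grid = k_grid, reps = reps, seed = seed,
                               metrics_k = metrics_k, bits = bits,
                               n_tuple = n_tuple, cost = cost,
                               standardize = standardize,
                               classifiers = classifiers))
  class(report) <- "evaluation_report"
  report
}

subset_table <- function(tab, rows) {
  feature_table(lapply(rows, function(i) tab$x[i, ]),
                tab$group[rows], tab$subjects[rows])
}

summarize_metrics <- function(conf) {
  per_rep <- conf[, {
    m <- binary_metrics(c(tp = tp, tn = tn, fp = fp, fn = fn))
    as.list(m)
  }, by = list(run, classifier, rep)]
  long <- data.table::melt(per_rep, id.vars = c("run", "classifier", "rep"),
                           variable.name = "metric")
  long[, list(mean = mean(value, na.rm = TRUE),
              sem = sd(value, na.rm = TRUE) / sqrt(sum(!is.na(value)))),
       by = list(run, classifier, metric)]
}

accuracy_contrast <- function(acc, k_grid, classifiers) {
  wide <- data.table::dcast(acc, classifier + k + rep ~ run,
                            value.var = "accuracy")
  out <- wide[, {
    d <- emotion - neutral
    p <- if (sd(d) == 0) 1 else t.test(d)$p.value
    list(mean_diff = mean(d), p = p)
  }, by = list(classifier, k)]
  out[, p_fdr := p.adjust(p, method = "BH"), by = classifier]
  out[]
}

#' Tally the top-feature selections by band and by cluster
#'
#' @param report an `evaluation_report`
#' @param run which run to tally (default "emotion")
#' @return list of two data.tables: `$band` and `$cluster` counts
#' @export
selection_tallies <- function(report, run = "emotion") {
  which_run <- run  # avoid NSE capture of the column of the same name
  sel <- report$selections[report$selections$run == which_run]
  parts <- data.table::tstrsplit(sel$key, "__")
  sel2 <- data.table::data.table(band = parts[[2]], cluster = parts[[3]])
  list(band = sel2[, list(n = .N), by = band][order(-n)],
       cluster = sel2[, list(n = .N), by = cluster][order(-n)])
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d reps, k in {%s}, classifiers: %s\n",
              x$params$reps, paste(range(x$params$k_grid), collapse = "..."),
              paste(x$params$classifiers, collapse = ", ")))
  agg <- x$accuracy[, list(mean_acc = mean(accuracy)),
                    by = list(run, classifier, k)]
  best <- agg[order(-mean_acc)][, head(.SD, 1), by = list(run, classifier)]
  print(best)
  invisible(x)
}

#' Feature-covariate correlation screen
#'
#' Pearson correlation and two-sided p-value of every feature against every
#' covariate, with an FDR-adjusted column. Constant covariates give NA
#' sentinels.
#'
#' @param table a `feature_table`
#' @param covariates data.frame of per-subject covariates (defaults to
#'   `table$covariates`)
#' @return data.table(feature, covariate, r, p, p_fdr, significant)
#' @export
covariate_correlation <- function(table, covariates = table$covariates) {
  if (is.null(covariates)) stop("no covariates supplied")
  stopifnot(nrow(covariates) == nrow(table$x))
  res <- list()
  for (cv in colnames(covariates)) {
    v <- covariates[[cv]]
    ok <- is.finite(v)
    if (sum(ok) < 3) stop("covariate ", cv, " has fewer than 3 values")
    for (f in colnames(table$x)) {
      x <- table$x[ok, f]
      if (sd(v[ok]) == 0 || sd(x) == 0) {
        res[[length(res) + 1L]] <- data.table::data.table(
          feature = f, covariate = cv, r = NA_real_, p = NA_real_)
      } else {
        ct <- cor.test(x, v[ok])
        res[[length(res) + 1L]] <- data.table::data.table(
          feature = f, covariate = cv, r = unname(ct$estimate),
          p = ct$p.value)
      }
    }
  }
  out <- data.table::rbindlist(res)
  out[, p_fdr := p.adjust(p, method = "BH")]
  out[, significant := !is.na(p) & p < 0.05]
  out[]
}

#' Write an evaluation report to files
#'
#' Writes machine-readable CSVs (accuracy per repetition, summary metrics,
#' top-feature selections, emotion-neutral contrast when present) and PDF
#' figures: accuracy versus feature count with SEM bars, and top-feature
#' tally histograms by band and cluster. Output is deterministic given the
#' report.
#'
#' @param report an `evaluation_report`
#' @param out_dir output directory (created if needed)
#' @return invisible vector of file paths
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$accuracy, "accuracy.csv")
  wr(report$metrics, "metrics.csv")
  wr(report$selections, "selections.csv")
  if (!is.null(report$contrast)) wr(report$contrast, "contrast.csv")
  agg <- report$accuracy[, list(mean = mean(accuracy),
                                sem = sd(accuracy) / sqrt(.N)),
                         by = list(run, classifier, k)]
  p <- file.path(out_dir, "accuracy_vs_k.pdf")
  grDevices::pdf(p, width = 8, height = 4)
  graphics::par(mfrow = c(1, length(unique(agg$classifier))))
  for (clf in unique(agg$classifier)) {
    sub <- agg[agg$classifier == clf]
    graphics::plot(NULL, xlim = range(sub$k), ylim = c(0.3, 1),
                   xlab = "number of features", ylab = "test accuracy",
                   main = clf)
    cols <- c(emotion = "steelblue", neutral = "darkorange")
    for (rn in unique(sub$run)) {
      s <- sub[sub$run == rn][order(k)]
      graphics::lines(s$k, s$mean, col = cols[[rn]], lwd = 2)
      graphics::arrows(s$k, s$mean - s$sem, s$k, s$mean + s$sem,
                       angle = 90, code = 3, length = 0.02,
                       col = cols[[rn]])
    }
    graphics::abline(h = 0.5, lty = 3)
    graphics::legend("bottomright", legend = unique(sub$run),
                     col = cols[unique(sub$run)], lwd = 2, bty = "n")
  }
  grDevices::dev.off()
  paths <- c(paths, p)
  tal <- selection_tallies(report)
  p2 <- file.path(out_dir, "top_feature_tallies.pdf")
  grDevices::pdf(p2, width = 8, height = 4)
  graphics::par(mfrow = c(1, 2))
  graphics::barplot(stats::setNames(tal$band$n, tal$band$band),
                    main = "top features by band", las = 2)
  graphics::barplot(stats::setNames(tal$cluster$n, tal$cluster$cluster),
                    main = "top features by cluster", las = 2)
  grDevices::dev.off()
  paths <- c(paths, p2)
  invisible(paths)
}
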