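#' Construct a normalized expression matrix with sample metadata
#'
#' @param values Numeric genes x samples matrix of normalized expression
#'   (TPM or RPKM), non-negative, with gene ids as rownames.
#' @param ages_days Per-sample ages in days post conception (> 0).
#' @param species Single species label for the whole matrix.
#' @param provenance `"individual"` or `"organoid"`.
#' @param unit Expression unit, `"TPM"` or `"RPKM"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, ages_days, species,
                              provenance = "individual", unit = "TPM") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            all(values >= 0), length(ages_days) == ncol(values),
            all(ages_days > 0), length(species) == 1)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  structure(list(values = values,
                 samples = data.frame(sample = colnames(values),
                                      age_days = ages_days,
                                      species = species,
                                      provenance = provenance,
                                      stringsAsFactors = FALSE),
                 unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", x$samples$species[1], ",", x$unit, ")\n")
  invisible(x)
}

#' Read / write an expression matrix
#'
#' Tab-separated genes x samples matrix with gene ids in the first column,
#' plus a CSV sidecar of sample metadata (`sample`, `age_days`, `species`,
#' `provenance`).  Sparse MTX triplet input is also accepted (`format =
#' "mtx"`, with `genes_path` listing gene ids, one per line).
#'
#' @param path Matrix file (TSV or MTX).
#' @param meta_path Sample-metadata CSV.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_path Gene-id file, required for MTX input.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, meta_path, format = c("tsv", "mtx"),
                                   genes_path = NULL) {
  format <- match.arg(format)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df[[1]]
  } else {
    if (is.null(genes_path)) stop("MTX input needs 'genes_path'")
    vals <- as.matrix(Matrix::readMM(path))
    rownames(vals) <- readLines(genes_path)
    colnames(vals) <- meta$sample
  }
  vals <- vals[, meta$sample, drop = FALSE]
  expression_matrix(vals, meta$age_days, meta$species[1],
                    provenance = meta$provenance[1] %||% "individual")
}

#' @rdname read_expression_matrix
#' @param expr An `expression_matrix` to write.
#' @export
write_expression_matrix <- function(expr, path, meta_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(expr$samples, meta_path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

predictor_families <- function() {
  c("elastic_net", "lasso", "svr", "knn", "random_forest",
    "gaussian_process")
}

log_features <- function(expr) t(log(expr$values + 1))

fit_family <- function(family, X, y) {
  n <- nrow(X)
  switch(family,
    lasso = glmnet::cv.glmnet(X, y, alpha = 1,
                              nfolds = min(5, n)),
    elastic_net = glmnet::cv.glmnet(X, y, alpha = 0.5,
                                    nfolds = min(5, n)),
    # constant genes cannot be scaled; leave them unscaled instead of warning
    svr = e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                     scale = apply(X, 2, stats::sd) > 0),
    knn = caret::knnreg(X, y, k = min(5, n - 1)),
    random_forest = randomForest::randomForest(X, y, ntree = 300),
    gaussian_process = kernlab::gausspr(X, y, kernel = "rbfdot",
                                        scaled = apply(X, 2, stats::sd) > 0))
}

predict_family <- function(family, model, X) {
  p <- switch(family,
    lasso = ,
    elastic_net = stats::predict(model, newx = X, s = "lambda.min"),
    svr = stats::predict(model, X),
    knn = stats::predict(model, X),
    random_forest = stats::predict(model, X),
    gaussian_process = kernlab::predict(model, X))
  as.numeric(p)
}

#' Train age-from-expression predictors and select the best family
#'
#' Splits samples into a training (~`split`) and a testing fraction, then
#' trains six regressor families on log-transformed expression
#' (`log(value + 1)`) against natural-log age: elastic-net- and
#' lasso-regularised linear models (regularisation tuned by internal
#' cross-validation), support-vector regression, k-nearest-neighbour,
#' random forest, and Gaussian-process regression.  Families are compared
#' by test-set RMSE in log-age units; the lowest-RMSE family is marked
#' selected.  A family that fails on a given dataset (e.g. too few
#' samples) is skipped with a warning.
#'
#' @param expr An [expression_matrix()] with known sample ages.
#' @param split Training fraction (default 0.7).
#' @param seed Integer seed for the split (results are deterministic
#'   given the seed).
#' @param families Subset of `predictor_families()` to train.
#' @return A `predictor_set`: `reports` (data frame `family`, `rmse`,
#'   `selected`), fitted `models`, the training `genes`, training-gene
#'   mean features for transfer imputation, and split indices.
#' @export
train_age_predictors <- function(expr, split = 0.7, seed = 1L,
                                 families = predictor_families()) {
  stopifnot(inherits(expr, "expression_matrix"),
            ncol(expr$values) >= 8, split > 0, split < 1)
  X <- log_features(expr)
  y <- log(expr$samples$age_days)
  n <- nrow(X)
  idx <- withr::with_seed(seed, sample(n, round(split * n)))
  models <- list()
  rmse <- stats::setNames(rep(NA_real_, length(families)), families)
  for (fam in families) {
    m <- tryCatch(withr::with_seed(seed, fit_family(fam, X[idx, , drop = FALSE], y[idx])),
                  error = function(e) {
                    warning("family '", fam, "' skipped: ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(m)) next
    pred <- predict_family(fam, m, X[-idx, , drop = FALSE])
    rmse[fam] <- sqrt(mean((pred - y[-idx])^2))
    models[[fam]] <- m
  }
  if (all(is.na(rmse))) stop("no predictor family could be trained")
  sel <- names(which.min(rmse))
  structure(list(reports = data.frame(family = names(rmse),
                                      rmse = unname(rmse),
                                      selected = names(rmse) == sel,
                                      stringsAsFactors = FALSE),
                 models = models, selected = sel,
                 genes = rownames(expr$values),
                 gene_means = colMeans(X[idx, , drop = FALSE]),
                 train_idx = idx, seed = seed,
                 species = expr$samples$species[1]),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat("Age predictors trained on", x$species, "(", length(x$genes),
      "genes ); selected:", x$selected, "\n")
  print(x$reports, row.names = FALSE)
  invisible(x)
}

#' Predict log age from expression with the selected family
#'
#' @param predictors A `predictor_set`.
#' @param expr Target [expression_matrix()]; genes are matched by id and
#'   training genes absent from the target are imputed at their training
#'   mean.
#' @param min_overlap Minimum fraction of training genes that must be
#'   present in the target.
#' @return Numeric vector of predicted natural-log ages.
#' @export
predict_log_age <- function(predictors, expr, min_overlap = 0.5) {
  stopifnot(inherits(predictors, "predictor_set"),
            inherits(expr, "expression_matrix"))
  shared <- intersect(predictors$genes, rownames(expr$values))
  if (length(shared) < min_overlap * length(predictors$genes))
    stop("gene overlap too small: ", length(shared), " of ",
         length(predictors$genes), " training genes in target")
  X <- matrix(rep(predictors$gene_means, each = ncol(expr$values)),
              ncol(expr$values), length(predictors$genes),
              dimnames = list(colnames(expr$values), predictors$genes))
  X[, shared] <- t(log(expr$values[shared, , drop = FALSE] + 1))
  predict_family(predictors$selected, predictors$models[[predictors$selected]], X)
}

#' Transfer ages from a target species via a trained predictor
#'
#' Applies the selected reference-species age predictor to another
#' species' (or organoids') expression: because the model was trained to
#' predict age in the reference species, its output is the
#' reference-species-equivalent age of each target sample.
#'
#' @param predictors A `predictor_set` trained on the reference species.
#' @param target Target [expression_matrix()].
#' @param min_overlap See [predict_log_age()].
#' @return A `transfer_pairs` data frame: `sample`, `source_age_days`,
#'   `translated_age_days`.
#' @export
transfer_ages <- function(predictors, target, min_overlap = 0.5) {
  pred <- predict_log_age(predictors, target, min_overlap)
  out <- data.frame(sample = target$samples$sample,
                    source_species = target$samples$species,
                    source_age_days = target$samples$age_days,
                    translated_age_days = exp(pred),
                    stringsAsFactors = FALSE)
  class(out) <- c("transfer_pairs", "data.frame")
  out
}

#' Convert transfer pairs to time-point rows
#'
#' Each transferred sample yields one `transcription` time point in the
#' source species (the source age) matched to the reference species (the
#' translated age) under a shared event id, ready for
#' [build_event_table()].
#'
#' @param pairs A `transfer_pairs` result.
#' @param reference_species Species the predictor was trained on.
#' @param provenance `"individual"` or `"organoid"`.
#' @return Data frame in the [read_timepoints()] column layout.
#' @export
transfer_to_timepoints <- function(pairs, reference_species,
                                   provenance = "individual") {
  stopifnot(inherits(pairs, "transfer_pairs"))
  ev <- paste0("transfer_", pairs$sample)
  base <- function(species, age) {
    data.frame(species = species, event_id = ev,
               event_type = "transcription", age_value = age,
               age_frame = "days_post_conception", sex = "pooled",
               population = "transfer", environment = "unknown",
               provenance = provenance, stringsAsFactors = FALSE)
  }
  rbind(base(pairs$source_species, pairs$source_age_days),
        base(reference_species, pairs$translated_age_days))
}

#' Correlation-based age alignment of one profile against a series
#'
#' Correlates one sample's log-transformed expression against every
#' sample of a reference series and reports the reference age of the
#' strongest correlation.  Only genes expressed above a floor in the
#' target profile enter (default `log10(expression) > 0.5`); both sides
#' are log10(x + 1)-transformed before the Pearson correlation.
#'
#' @param target_profile Named numeric vector (gene -> expression) of the
#'   sample to place.
#' @param reference An [expression_matrix()] spanning the candidate ages.
#' @param min_log10_expr Expression floor applied to the target profile.
#' @return List with `best_age` (days), `best_sample`, `tie` (whether
#'   the maximum was tied; the youngest age is returned), and `profile`
#'   (data frame `sample`, `age_days`, `correlation` for plotting).
#' @export
correlation_align <- function(target_profile, reference,
                              min_log10_expr = 0.5) {
  stopifnot(!is.null(names(target_profile)),
            inherits(reference, "expression_matrix"))
  keep <- names(target_profile)[log10(target_profile) > min_log10_expr]
  shared <- intersect(keep, rownames(reference$values))
  if (length(shared) < 100)
    warning("only ", length(shared), " genes survive the expression filter")
  if (length(shared) < 3) stop("too few genes to correlate")
  x <- log10(target_profile[shared] + 1)
  R <- log10(reference$values[shared, , drop = FALSE] + 1)
  r <- as.numeric(stats::cor(x, R))
  prof <- data.frame(sample = colnames(reference$values),
                     age_days = reference$samples$age_days,
                     correlation = r, stringsAsFactors = FALSE)
  best <- which(r == max(r))
  tie <- length(best) > 1
  if (tie) best <- best[which.min(prof$age_days[best])]
  list(best_age = prof$age_days[best], best_sample = prof$sample[best],
       tie = tie, profile = prof)
}
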