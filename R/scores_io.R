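# On-disk formats: TSV site-score tables and key-value model files.
# All text is UTF-8 with '.' as decimal separator; score and p-value columns
# are printed with 6 significant digits.

SCORE_COLUMNS <- c("family_id", "column", "test", "lnl_null", "lnl_alt",
                   "scale", "pvalue", "score")

#' Write a site-score table
#'
#' Tab-separated with header `family_id column test lnl_null lnl_alt scale
#' pvalue score`; `pvalue` and `score` are rounded to 6 significant digits.
#'
#' @param scores site-score `data.frame` (see [indel_rate_test()]).
#' @param path output file.
#' @export
write_site_scores <- function(scores, path) {
  stopifnot(all(SCORE_COLUMNS %in% names(scores)))
  out <- data.table::as.data.table(scores[, SCORE_COLUMNS])
  out$pvalue <- signif(out$pvalue, 6)
  out$score <- signif(out$score, 6)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a site-score table
#' @param path a TSV written by [write_site_scores()].
#' @return a site-score `data.frame`.
#' @export
read_site_scores <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("family_id",
                                                          "test")))
  unknown <- setdiff(names(dt), SCORE_COLUMNS)
  if (length(unknown) > 0) {
    stop("unknown column(s) in score table: ", paste(unknown, collapse = ", "))
  }
  if (!all(SCORE_COLUMNS %in% names(dt))) {
    stop("score table is missing column(s): ",
         paste(setdiff(SCORE_COLUMNS, names(dt)), collapse = ", "))
  }
  as.data.frame(dt)[, SCORE_COLUMNS]
}

#' Stream a site-score table in constant memory
#'
#' Reads the file in chunks of `chunk_size` rows and calls `fun(chunk)` on
#' each data-frame chunk; only one chunk is held in memory at a time.
#'
#' @param path a TSV written by [write_site_scores()].
#' @param fun callback taking a data-frame chunk.
#' @param chunk_size rows per chunk.
#' @return invisibly, the total number of rows streamed.
#' @export
stream_site_scores <- function(path, fun, chunk_size = 10000L) {
  con <- file(path, open = "r")
  on.exit(close(con))
  header <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1]]
  unknown <- setdiff(header, SCORE_COLUMNS)
  if (length(unknown) > 0) {
    stop("unknown column(s) in score table: ", paste(unknown, collapse = ", "))
  }
  total <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0) break
    parts <- strsplit(lines, "\t", fixed = TRUE)
    chunk <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(chunk) <- header
    for (nm in setdiff(SCORE_COLUMNS, c("family_id", "test"))) {
      chunk[[nm]] <- as.numeric(chunk[[nm]])
    }
    chunk$column <- as.integer(chunk$column)
    fun(chunk)
    total <- total + nrow(chunk)
  }
  invisible(total)
}

#' Write a fitted model as a key-value text file
#'
#' One `key<TAB>value` pair per line.  Provenance fields (`dataset_hash`,
#' `filter_threshold`, `created`, `package_version`) are always written.
#'
#' @param fit an `ip_fit` from [fit_model()], or a bare model object.
#' @param path output file.
#' @param dataset_hash provenance hash of the fitted data (computed by
#'   [fit_model()] callers; defaults to `"NA"`).
#' @param filter_threshold gap-run filter used to build the dataset
#'   (provenance; default `"NA"`).
#' @param di_ratio optional deletion/insertion ratio to record.
#' @export
write_model_file <- function(fit, path, dataset_hash = NA,
                             filter_threshold = NA, di_ratio = NULL) {
  model <- if (inherits(fit, "ip_fit")) fit$model else fit
  kv <- list()
  if (inherits(model, "f84_params")) {
    kv$model <- "F84"
    kv$alpha <- model$alpha
    kv$beta <- model$beta
    for (i in 1:4) kv[[paste0("pi_", ALPHA5[i])]] <- model$pi[i]
  } else if (inherits(model, "indel_model")) {
    kv$model <- "F84E_RELAXED"
    kv$alpha <- model$f84$alpha
    kv$beta <- model$f84$beta
    kv$lambda <- model$lambda
    kv$mu <- model$mu
    kv$p <- model$p
    for (i in 1:4) kv[[paste0("pi_", ALPHA5[i])]] <- model$f84$pi[i]
  } else if (inherits(model, "hkyg_params")) {
    kv$model <- "HKYG"
    kv$kappa <- model$kappa
    kv$sigma <- model$sigma
    for (i in 1:4) kv[[paste0("pi_", ALPHA5[i])]] <- model$pi5[i]
    kv$pi_gap <- model$pi5[5]
  } else stop("unsupported model object")
  if (inherits(fit, "ip_fit")) {
    kv$loglik <- fit$loglik
    kv$converged <- fit$converged
  }
  if (!is.null(di_ratio)) kv$di_ratio <- di_ratio
  kv$dataset_hash <- as.character(dataset_hash)
  kv$filter_threshold <- as.character(filter_threshold)
  kv$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  kv$package_version <- as.character(utils::packageVersion("indelphase"))
  vals <- vapply(kv, function(v) {
    if (is.numeric(v)) format(v, digits = 17) else as.character(v)
  }, "")
  writeLines(paste(names(kv), vals, sep = "\t"), path)
  invisible(path)
}

#' Read a key-value model file
#' @param path file written by [write_model_file()].
#' @return list with `model` (reconstructed model object), `kind` and
#'   `metadata` (all remaining key-value pairs).
#' @export
read_model_file <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop("malformed model file line(s): ",
                     paste(which(bad), collapse = ", "))
  kv <- stats::setNames(vapply(parts, `[`, "", 2L),
                        vapply(parts, `[`, "", 1L))
  num <- function(nm) as.numeric(kv[[nm]])
  kind <- kv[["model"]]
  pi <- c(num("pi_A"), num("pi_C"), num("pi_G"), num("pi_T"))
  model <- switch(kind,
    F84 = f84_params(num("alpha"), num("beta"), pi),
    F84E_RELAXED = indel_model(num("lambda"), num("mu"),
                               f84_params(num("alpha"), num("beta"), pi),
                               num("p")),
    HKYG = hkyg_params(num("kappa"), num("sigma"), c(pi, num("pi_gap"))),
    stop("unknown model kind in file: ", kind))
  meta <- as.list(kv[setdiff(names(kv),
                             c("model", "alpha", "beta", "lambda", "mu", "p",
                               "kappa", "sigma", "pi_A", "pi_C", "pi_G",
                               "pi_T", "pi_gap"))])
  list(model = model, kind = kind, metadata = meta)
}

# provenance hash of an alignment set's contents
dataset_hash <- function(aset) {
  rlang::hash(lapply(aset, function(p) {
    list(p$alignment$family_id, p$alignment$seqs, tree_key(p$tree))
  }))
}
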