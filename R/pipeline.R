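# End-to-end workflows: encode, ratio sweep, IFS, prediction. These back
# the command-line interface (inst/cli/aquapred) and are usable directly
# from R. Progress goes to stderr; results go to files / return values.

log_msg <- function(...) message("[aquapred] ", sprintf(...))

#' Encode a positive/negative FASTA pair into a labelled feature matrix
#'
#' Reads both files, validates and deduplicates records, encodes every
#' sequence into the 188D descriptor and (optionally) writes the matrix as
#' CSV.
#'
#' @param pos_fasta,neg_fasta FASTA paths for positives and negatives.
#' @param out Optional output CSV path.
#' @return A labelled `feature_matrix` (invisibly if `out` is given).
#' @export
pipeline_encode <- function(pos_fasta, neg_fasta, out = NULL) {
  pos <- dedupe_exact(read_fasta(pos_fasta, label = 1L))
  neg <- dedupe_exact(read_fasta(neg_fasta, label = 0L))
  log_msg("read %d positives (%d duplicates removed), %d negatives (%d removed)",
          nrow(pos), attr(pos, "removed"), nrow(neg), attr(neg, "removed"))
  fm <- encode_matrix(rbind(pos, neg))
  log_msg("encoded %d x %d feature matrix", nrow(fm$x), ncol(fm$x))
  if (!is.null(out)) {
    write_feature_matrix(fm, out)
    log_msg("wrote %s", out)
    return(invisible(fm))
  }
  fm
}

#' Class-ratio sweep with cross-validated classifiers
#'
#' For every combination of class ratio and classifier family, assembles a
#' dataset (all positives + ratio-many subsampled negatives), runs
#' stratified k-fold cross-validation and reports the mean Sn, Sp, Acc,
#' MCC and AUROC. Ratios that exceed the negative pool are skipped with a
#' logged reason.
#'
#' @param pos,neg Validated record data frames (positive / negative pools).
#' @param ratios Vector of positive integers and/or `"all"`.
#' @param families Classifier family names (see [classifier_spec()]).
#' @param k CV folds (default 10).
#' @param seed Master seed (assembly and CV seeds derive from it).
#' @param out Optional TSV output path.
#' @return Data frame: ratio, family, Sn, Sp, Acc, MCC, AUROC, seed.
#' @export
pipeline_ratio_sweep <- function(pos, neg, ratios = c(1L, 2L),
                                 families = "random_forest", k = 10L,
                                 seed = 42L, out = NULL) {
  schema <- encoder_schema()
  rows <- list()
  for (ratio in ratios) {
    recs <- tryCatch(assemble(pos, neg, ratio, seed = seed),
                     error = function(e) {
                       log_msg("skipping ratio %s: %s", ratio,
                               conditionMessage(e))
                       NULL
                     })
    if (is.null(recs)) next
    fm <- encode_matrix(recs, schema)
    for (family in families) {
      rep_ <- stratified_kfold(fm, classifier_spec(family, seed = seed),
                               k = k, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        ratio = as.character(ratio), family = family,
        t(rep_$mean), seed = seed, stringsAsFactors = FALSE)
      log_msg("ratio 1:%s %s: Acc %.2f, AUROC %.4f", ratio, family,
              rep_$mean["Acc"], rep_$mean["AUROC"])
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(out)) {
    write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("wrote %s", out)
  }
  report
}

#' ANOVA ranking + incremental feature selection workflow
#'
#' Ranks features by ANOVA F-score, sweeps prefix sizes by cross-validated
#' accuracy, and retrains a final model on the optimal prefix.
#'
#' @param fm A labelled `feature_matrix`.
#' @param spec A [classifier_spec()].
#' @param d_grid Prefix sizes to evaluate (default every size).
#' @param k CV folds.
#' @param seed CV seed.
#' @param out_prefix Optional path prefix; writes `<prefix>_ranking.tsv`,
#'   `<prefix>_ifs.tsv` and `<prefix>_model.rds`.
#' @return List with `ranking`, `ifs` (an `ifs_result`) and `model`
#'   (trained on the optimal prefix).
#' @export
pipeline_ifs <- function(fm, spec = classifier_spec("random_forest"),
                         d_grid = seq_len(ncol(fm$x)), k = 10L, seed = 42L,
                         out_prefix = NULL) {
  ranking <- anova_f(fm)
  ifs <- ifs_search(fm, ranking, spec, d_grid = d_grid, k = k, seed = seed)
  log_msg("IFS optimum: d = %d (%s %.3f)", ifs$optimal_d, ifs$objective,
          ifs$optimal_score)
  model <- train(select_top(fm, ranking, ifs$optimal_d), spec)
  if (!is.null(out_prefix)) {
    write_ranking(ranking, paste0(out_prefix, "_ranking.tsv"))
    write.table(ifs$curve, paste0(out_prefix, "_ifs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    save_model(model, paste0(out_prefix, "_model.rds"))
    log_msg("wrote %s_{ranking,ifs}.tsv and %s_model.rds", out_prefix,
            out_prefix)
  }
  list(ranking = ranking, ifs = ifs, model = model)
}

#' Predict aquaporin class for FASTA sequences
#'
#' Encodes the input sequences, restricts the descriptor to the model's
#' feature contract and writes per-sequence scores and labels.
#'
#' @param model An `aqp_model` or path to a saved model file.
#' @param fasta FASTA path of query sequences.
#' @param out Optional TSV output path (columns id, score, label).
#' @return Prediction data frame; rejected input ids in the `"rejected"`
#'   attribute.
#' @export
pipeline_predict <- function(model, fasta, out = NULL) {
  if (is.character(model)) model <- load_model(model)
  recs <- read_fasta(fasta)
  fm <- encode_matrix(recs)
  keep <- match(model$feature_names, colnames(fm$x))
  if (anyNA(keep))
    stop("model features missing from the encoder schema: ",
         model$feature_names[which(is.na(keep))[1]])
  pred <- predict(model, feature_matrix(fm$x[, keep, drop = FALSE]))
  attr(pred, "rejected") <- attr(recs, "rejected")
  log_msg("predicted %d sequences (%d positive calls)", nrow(pred),
          sum(pred$label))
  if (!is.null(out)) {
    write.table(pred, out, sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("wrote %s", out)
  }
  pred
}

#' Write a machine-readable run manifest
#'
#' Records inputs, seeds, parameters and the package version for a CLI
#' run, so equal manifests imply equal outputs.
#'
#' @param path Output JSON path.
#' @param params Named list of run parameters.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params) {
  payload <- list(package = "aquapred",
                  version = as.character(utils::packageVersion("aquapred")),
                  params = params)
  payload$config_hash <- digest_params(params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# polynomial rolling hash over the canonical JSON encoding; avoids an
# extra dependency for a fingerprint that only needs to detect config
# drift (not adversarial collisions)
digest_params <- function(params) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(params,
                                                   auto_unbox = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967296  # exact in doubles
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
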