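# Feature/strategy ablation: retrain with one toggle off at a time and
# report the mention-level F drop relative to the full model.

#' Ablation analysis of features and strategies
#'
#' Fits the full model, then refits with each single toggle turned off
#' (character-level representation, lexicon feature, the MLS auxiliary
#' objective, or the post-processing step, which is toggled at prediction
#' time rather than refit), and evaluates each on the test documents.
#'
#' @param train,test Document lists (test needs gold mentions).
#' @param lexicon An `mcnn_lexicon` or `NULL`.
#' @param config Base [mcnn_config()].
#' @param toggles Which axes to ablate.
#' @param dev Optional development documents for epoch selection.
#' @param verbose Print progress.
#' @return data.frame with columns `feature` ("none" = full model),
#'   `precision`, `recall`, `f` (percent scale) and `delta` (F drop vs the
#'   full model).
#' @export
ablate <- function(train, test, lexicon = NULL, config = mcnn_config(),
                   toggles = c("char", "lexicon", "mls", "postprocess"),
                   dev = NULL, verbose = FALSE) {
  toggles <- match.arg(toggles, several.ok = TRUE)
  gold <- do.call(rbind, lapply(test, function(d) d$mentions))
  evaluate <- function(fit, postprocess = TRUE) {
    pred <- predict(fit, test, type = "mentions", postprocess = postprocess,
                    abbrev = postprocess)
    prf <- mention_prf(pred, gold)
    c(precision = 100 * prf$precision, recall = 100 * prf$recall,
      f = 100 * prf$f)
  }
  fit_full <- mcnn(train, dev = dev, lexicon = lexicon, config = config,
                   verbose = verbose)
  rows <- list()
  full <- evaluate(fit_full)
  rows[["none"]] <- full
  for (t in toggles) {
    if (t == "postprocess") {
      # post-processing is a prediction-time step; no refit needed
      rows[[t]] <- evaluate(fit_full, postprocess = FALSE)
      next
    }
    cfg <- config
    if (t == "char") cfg$use_char <- FALSE
    if (t == "lexicon") cfg$use_lexicon <- FALSE
    if (t == "mls") cfg$mls <- FALSE
    fit <- mcnn(train, dev = dev, lexicon = lexicon, config = cfg,
                verbose = verbose)
    rows[[t]] <- evaluate(fit)
  }
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    data.frame(feature = nm, precision = rows[[nm]]["precision"],
               recall = rows[[nm]]["recall"], f = rows[[nm]]["f"],
               delta = full["f"] - rows[[nm]]["f"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$delta[out$feature == "none"] <- 0
  out
}
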