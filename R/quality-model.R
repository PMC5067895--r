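# Aggregation of metric quality scores into subcharacteristic and
# characteristic scores. The shipped default model is the published core
# subset of the SQuaRE-derived OQuaRE association table (five characteristics
# and their printed subcharacteristic-to-metric mappings); the mapping is a
# configurable contract, so site-specific models can be loaded from YAML.

DEFAULT_MODEL <- list(
  Structural = list(
    "Formal relations support" = list(RROnto = 1),
    "Tangledness" = list(TMOnto = 1),
    "Cohesion" = list(LCOMOnto = 1)
  ),
  `Functional adequacy` = list(
    "Controlled vocabulary" = list(ANOnto = 1),
    "Inference" = list(RROnto = 1, CROnto = 1),
    "Consistent search and query" = list(ANOnto = 1, RROnto = 1, AROnto = 1, INROnto = 1),
    "Knowledge acquisition and representation" = list(ANOnto = 1, RROnto = 1, NOMOnto = 1)
  ),
  Maintainability = list(
    "Modularity" = list(WMCOnto = 1, CBOnto = 1),
    "Analysability" = list(WMCOnto = 1, DITOnto = 1, RFCOnto = 1, NOMOnto = 1,
                           LCOMOnto = 1, CBOnto = 1),
    "Modification stability" = list(WMCOnto = 1, NOCOnto = 1, RFCOnto = 1,
                                    LCOMOnto = 1, CBOnto = 1)
  ),
  Reliability = list(
    "Recoverability" = list(WMCOnto = 1, DITOnto = 1, NOMOnto = 1, LCOMOnto = 1),
    "Availability" = list(LCOMOnto = 1)
  ),
  Operability = list(
    "Learnability" = list(WMCOnto = 1, LCOMOnto = 1, RFCOnto = 1, NOMOnto = 1,
                          CBOnto = 1, NOCOnto = 1)
  )
)

#' Quality model configuration
#'
#' A quality model maps each subcharacteristic to a weighted list of metrics
#' and each characteristic to its subcharacteristics. `oq_quality_model()`
#' returns the shipped default (equal weights); `read_quality_model()` loads
#' a model from YAML of the form
#' `characteristic: {subcharacteristic: {metric: weight, ...}, ...}`.
#'
#' @param x For `read_quality_model`, a YAML file path.
#' @return An `oquare_quality_model`: a tibble with columns `characteristic`,
#'   `subcharacteristic`, `metric`, `weight`.
#' @export
oq_quality_model <- function() {
  model_from_list(DEFAULT_MODEL)
}

#' @rdname oq_quality_model
#' @export
read_quality_model <- function(x) {
  model_from_list(yaml::read_yaml(x))
}

#' @rdname oq_quality_model
#' @param model A quality model.
#' @param path Output YAML path.
#' @export
write_quality_model <- function(model, path) {
  nested <- lapply(split(model, model$characteristic), function(ch) {
    lapply(split(ch, ch$subcharacteristic),
           function(s) as.list(setNames(s$weight, s$metric)))
  })
  yaml::write_yaml(nested, path)
  invisible(path)
}

model_from_list <- function(lst) {
  out <- purrr::imap(lst, function(subs, ch) {
    purrr::imap(subs, function(ms, sub) {
      tibble::tibble(characteristic = ch, subcharacteristic = sub,
                     metric = names(ms), weight = as.numeric(unlist(ms)))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  bad <- setdiff(out$metric, oq_metric_ids())
  if (length(bad) > 0) abort(paste0("quality model references unknown metric(s): ",
                                    paste(unique(bad), collapse = ", ")))
  if (any(out$weight <= 0)) abort("quality model weights must be positive")
  structure(out, class = c("oquare_quality_model", class(out)))
}

#' Subcharacteristic quality scores
#'
#' Each subcharacteristic scores the weighted mean of its metrics' quality
#' scores. Undefined metric scores are dropped with a warning and the
#' remaining weights renormalised; a subcharacteristic with no defined metric
#' is reported `NA`.
#'
#' @param scores Tibble with columns `metric`, `score` (see [score_vector()]).
#' @param model An `oquare_quality_model` (default [oq_quality_model()]).
#' @return Tibble `characteristic`, `subcharacteristic`, `score`.
#' @export
subcharacteristic_scores <- function(scores, model = oq_quality_model()) {
  stopifnot(is.data.frame(scores), all(c("metric", "score") %in% names(scores)))
  joined <- dplyr::left_join(model, scores[c("metric", "score")], by = "metric")
  if (anyNA(joined$score)) {
    warn("undefined metric scores dropped from aggregation (weights renormalised)")
  }
  joined |>
    dplyr::group_by(.data$characteristic, .data$subcharacteristic) |>
    dplyr::summarise(score = {
      ok <- !is.na(.data$score)
      if (!any(ok)) NA_real_ else
        sum(.data$score[ok] * .data$weight[ok]) / sum(.data$weight[ok])
    }, .groups = "drop")
}

#' Characteristic quality scores
#'
#' Unweighted mean of the constituent subcharacteristic scores.
#'
#' @param sub Tibble from [subcharacteristic_scores()].
#' @return Tibble `characteristic`, `score`.
#' @export
characteristic_scores <- function(sub) {
  sub |>
    dplyr::group_by(.data$characteristic) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(score = ifelse(is.nan(.data$score), NA_real_, .data$score))
}

#' Full quality report for one score vector
#'
#' @param scores Tibble with columns `metric`, `score`.
#' @param model An `oquare_quality_model`.
#' @return An `oquare_quality_report` list with elements `subcharacteristics`,
#'   `characteristics` (tibbles) and `overall` (mean of characteristic
#'   scores).
#' @export
quality_report <- function(scores, model = oq_quality_model()) {
  sub <- subcharacteristic_scores(scores, model)
  ch <- characteristic_scores(sub)
  overall <- mean(ch$score, na.rm = TRUE)
  structure(
    list(subcharacteristics = sub, characteristics = ch,
         overall = if (is.nan(overall)) NA_real_ else overall),
    class = "oquare_quality_report"
  )
}

#' @export
print.oquare_quality_report <- function(x, ...) {
  cat("<oquare_quality_report>\n")
  cat("Characteristics:\n")
  for (i in seq_len(nrow(x$characteristics))) {
    cat(sprintf("  %-22s %.2f\n", x$characteristics$characteristic[[i]],
                x$characteristics$score[[i]]))
  }
  cat(sprintf("Overall mean: %.2f\n", x$overall))
  invisible(x)
}

#' @export
tidy.oquare_quality_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$subcharacteristics, level = "subcharacteristic",
                  .before = 1),
    dplyr::mutate(dplyr::rename(x$characteristics,
                                characteristic = "characteristic"),
                  level = "characteristic", subcharacteristic = NA_character_,
                  .before = 1),
    tibble::tibble(level = "overall", characteristic = NA_character_,
                   subcharacteristic = NA_character_, score = x$overall)
  )
}
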