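# Precision/recall evaluation of mutation grounding and mutant-impact
# relation extraction against gold-standard annotations.

#' Read a gold-standard TSV
#'
#' Columns: `doc_id`, `record_type` ("mutation" or "relation"), `mutation`
#' (normalized wNm), `accession`, `position`, `direction`, `property_key`.
#' Mutation records use the first five columns; relation records use
#' doc_id/mutation/direction/property_key.
#'
#' @param path Path to the TSV file.
#' @return A list with data.frames `mutations` and `relations`.
#' @export
read_gold_standard <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  needed <- c("doc_id", "record_type", "mutation", "accession", "position",
              "direction", "property_key")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("gold standard is missing columns: ", paste(missing, collapse = ", "))
  mut <- df[df$record_type == "mutation",
            c("doc_id", "mutation", "accession", "position"), drop = FALSE]
  mut$position <- as.integer(mut$position)
  rel <- df[df$record_type == "relation",
            c("doc_id", "mutation", "direction", "property_key"), drop = FALSE]
  list(mutations = unique(mut), relations = unique(rel))
}

#' Write a gold standard to TSV
#' @param gold A list with `mutations` and `relations` data.frames.
#' @param path Output path.
#' @export
write_gold_standard <- function(gold, path) {
  mut <- gold$mutations
  rel <- gold$relations
  rows <- rbind(
    data.frame(doc_id = mut$doc_id, record_type = "mutation",
               mutation = mut$mutation, accession = mut$accession,
               position = as.character(mut$position), direction = "",
               property_key = "", stringsAsFactors = FALSE),
    data.frame(doc_id = rel$doc_id, record_type = "relation",
               mutation = rel$mutation, accession = "", position = "",
               direction = rel$direction, property_key = rel$property_key,
               stringsAsFactors = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

metric_result <- function(tp, n_pred, n_gold) {
  list(precision = if (n_pred > 0L) tp / n_pred else 0,
       recall = tp / n_gold,
       precision_defined = n_pred > 0L,
       tp = tp, n_pred = n_pred, n_gold = n_gold)
}

#' Mutation-grounding precision and recall
#'
#' Precision is the number of correctly grounded mutations over all grounded
#' mutations; recall is the number of correctly grounded mutations over all
#' uniquely mentioned gold mutations. A prediction is correct when document,
#' normalized mutation, accession and grounded sequence position all match.
#' Counts are micro-averaged over documents with set semantics (duplicate
#' predictions never change counts). With zero predictions the precision is
#' undefined and reported as 0 with `precision_defined = FALSE`.
#'
#' @param pred Data.frame with `doc_id`, `mutation`, `accession`, `position`
#'   (from [collect_grounding_predictions()]).
#' @param gold Gold standard list (see [read_gold_standard()]).
#' @return List with `precision`, `recall`, `precision_defined`, `tp`,
#'   `n_pred`, `n_gold`.
#' @export
grounding_metrics <- function(pred, gold) {
  gm <- unique(gold$mutations)
  if (nrow(gm) == 0L) stop("empty gold standard: recall undefined")
  pred <- unique(pred[, c("doc_id", "mutation", "accession", "position")])
  gk <- paste(gm$doc_id, gm$mutation, gm$accession, gm$position, sep = "\r")
  pk <- paste(pred$doc_id, pred$mutation, pred$accession, pred$position,
              sep = "\r")
  metric_result(sum(pk %in% gk), length(pk), length(gk))
}

#' Mutant-impact relation precision and recall
#'
#' A predicted relation is correct only when all parts match a gold
#' relation: the causal mutation, the direction of the impact and the
#' impacted property (compared by GO id for grounded function properties,
#' by variable name for kinetic variables). Micro-averaged with set
#' semantics.
#'
#' @param pred Data.frame with `doc_id`, `mutation`, `direction`,
#'   `property_key` (from [collect_relation_predictions()]).
#' @param gold Gold standard list.
#' @return List as in [grounding_metrics()].
#' @export
relation_metrics <- function(pred, gold) {
  gr <- unique(gold$relations)
  if (nrow(gr) == 0L) stop("empty gold standard: recall undefined")
  pred <- unique(pred[, c("doc_id", "mutation", "direction", "property_key")])
  gk <- paste(gr$doc_id, gr$mutation, gr$direction, gr$property_key,
              sep = "\r")
  pk <- paste(pred$doc_id, pred$mutation, pred$direction, pred$property_key,
              sep = "\r")
  metric_result(sum(pk %in% gk), length(pk), length(gk))
}
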