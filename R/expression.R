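#' Per-gene weight measures over a sample cohort
#'
#' Computes, for every gene, the three statistics used as edge-weight
#' measures: the mean, the median, and `sv`, the standard deviation of the
#' gene's expression vector across samples (sample form, denominator n-1;
#' defined as 0 for a single sample). These summarise how strongly and how
#' variably each enzyme-coding gene is expressed in the cohort.
#'
#' @param expression Expression tibble (`gene` column plus one numeric column
#'   per sample) as returned by [read_expression_matrix()].
#' @return A `weight_tbl` tibble with columns `gene`, `mean`, `median`, `sv`
#'   and `n_samples`, one row per gene.
#' @examples
#' m <- tibble::tibble(gene = c("G1", "G2"), s1 = c(4, 1), s2 = c(4, 3))
#' summarize_expression(m)
#' @export
summarize_expression <- function(expression) {
  stopifnot(names(expression)[1] == "gene", ncol(expression) >= 2)
  vals <- as.matrix(expression[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  n <- ncol(vals)
  sv <- if (n == 1) rep(0, nrow(vals)) else apply(vals, 1, sd)
  out <- tibble::tibble(
    gene = expression$gene,
    mean = rowMeans(vals),
    median = apply(vals, 1, median),
    sv = sv,
    n_samples = n
  )
  class(out) <- c("weight_tbl", class(out))
  out
}

#' Drop unexpressed genes from a weight table
#'
#' Removes genes whose cohort mean expression falls strictly below
#' `threshold` (default 1), so that effectively unexpressed enzymes cannot
#' contribute edges to the network. A gene with mean exactly equal to the
#' threshold is kept.
#'
#' @param weights A `weight_tbl` from [summarize_expression()].
#' @param threshold Non-negative minimum mean expression (default 1).
#' @return The subset of `weights` with `mean >= threshold`.
#' @export
filter_unexpressed <- function(weights, threshold = 1) {
  stopifnot(is.numeric(threshold), threshold >= 0)
  dplyr::filter(weights, .data$mean >= threshold)
}

#' Fold-change classification of a user cohort against a reference
#'
#' For every gene in the user cohort, computes
#' `fold_change = (value + pseudocount) / (reference mean + pseudocount)` and
#' classifies it: `up` when the fold change is strictly greater than 2,
#' `down` when strictly less than 0.5, `neutral` otherwise. Genes absent from
#' the reference, or with a zero denominator under a zero pseudocount, are
#' classified `undefined` rather than given a fabricated call. In rendered
#' route tables, up-regulated enzymes are marked red and down-regulated
#' green.
#'
#' @param user User cohort tibble (`gene`, `value`) from [read_user_cohort()].
#' @param reference A `weight_tbl` for the reference cohort.
#' @param pseudocount Non-negative value added to numerator and denominator
#'   (default 0; opt-in only).
#' @return A `fold_change_tbl` tibble with columns `gene`, `value`,
#'   `reference_mean`, `fold_change` and `class`.
#' @examples
#' user <- tibble::tibble(gene = "GFPT1", value = 10)
#' ref <- summarize_expression(tibble::tibble(gene = "GFPT1", s1 = 4, s2 = 4))
#' compute_fold_changes(user, ref)
#' @export
compute_fold_changes <- function(user, reference, pseudocount = 0) {
  stopifnot(is.numeric(pseudocount), pseudocount >= 0)
  ref <- tibble::tibble(gene = reference$gene, reference_mean = reference$mean)
  out <- dplyr::left_join(
    tibble::tibble(gene = user$gene, value = user$value), ref, by = "gene"
  )
  denom <- out$reference_mean + pseudocount
  fc <- (out$value + pseudocount) / denom
  fc[is.na(out$reference_mean) | denom == 0] <- NA_real_
  out$fold_change <- fc
  out$class <- dplyr::case_when(
    is.na(fc) ~ "undefined",
    fc > 2 ~ "up",
    fc < 0.5 ~ "down",
    TRUE ~ "neutral"
  )
  class(out) <- c("fold_change_tbl", class(out))
  out
}

#' Map regulation classes to display colours
#'
#' Up-regulated enzymes are rendered red, down-regulated green; everything
#' else is unmarked.
#'
#' @param class Character vector of classes from [compute_fold_changes()].
#' @return Character vector of `"red"`, `"green"` or `""`.
#' @export
regulation_colour <- function(class) {
  dplyr::case_when(class == "up" ~ "red", class == "down" ~ "green",
                   TRUE ~ "")
}

#' @exportS3Method
autoplot.fold_change_tbl <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$fold_change))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$reference_mean,
                                    y = .data$fold_change,
                                    colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.5, 2), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(up = "red", down = "darkgreen",
                                            neutral = "grey40")) +
    ggplot2::labs(x = "reference mean expression",
                  y = "fold change (user / reference)",
                  colour = "regulation")
}

#' @exportS3Method
autoplot.weight_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean, y = .data$sv)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean expression (log scale)",
                  y = "sv (standard deviation across samples)")
}
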