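#' Mixed-design ANOVA for two within-subject factors and one optional
#' between-subjects factor
#'
#' Classical univariate mixed-model partition for a design with one
#' observation per subject in every within-cell: the between-subjects
#' factor is tested against subjects-within-groups; every within effect is
#' tested against its own effect-by-subjects-within-groups error stratum.
#' Sums of squares are the sequential (weighted-means) partition computed
#' from marginal totals, which coincides with the classical textbook
#' partition and with `stats::aov()` Error-strata output; with unequal
#' group sizes the weighted marginal means are used. Effect sizes are
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame.
#' @param dv,id,within1,within2 Column names (strings) of the dependent
#'   variable, subject identifier, and the two within-subject factors.
#' @param between Column name of the between-subjects factor, or `NULL`
#'   for a fully within-subjects design.
#' @return A tibble with one row per effect: `effect`, `df1`, `df2`, `ss`,
#'   `ss_error`, `F`, `p`, `partial_eta_sq`.
#' @export
mixed_anova <- function(data, dv, id, within1, within2, between = NULL) {
  y <- data[[dv]]
  if (anyNA(y)) stop("missing cells are not allowed", call. = FALSE)
  subj <- factor(data[[id]])
  w1 <- factor(data[[within1]])
  w2 <- factor(data[[within2]])
  grp <- if (is.null(between)) factor(rep("all", nrow(data)))
         else factor(data[[between]])

  s <- nlevels(w1); v <- nlevels(w2); p_cells <- s * v
  # completeness: every subject contributes exactly one obs per within cell
  counts <- table(subj, w1, w2)
  if (any(counts != 1L)) {
    stop("each subject needs exactly one observation per within-subject cell",
         call. = FALSE)
  }
  subj_group <- tapply(as.character(grp), subj, function(x) {
    ux <- unique(x)
    if (length(ux) != 1L) stop("subject assigned to several groups",
                               call. = FALSE)
    ux
  })
  N <- nlevels(subj)
  n_g <- table(factor(subj_group, levels = levels(grp)))
  g <- nlevels(grp)

  tot <- function(...) tapply(y, list(...), sum)
  T_all <- sum(y)
  C <- T_all^2 / (p_cells * N)
  T_g <- tapply(y, grp, sum)
  A_g <- sum(T_g^2 / (p_cells * as.numeric(n_g)))     # group reduction
  ss_k <- A_g - C
  T_i <- tapply(y, subj, sum)
  ss_bsub <- sum(T_i^2) / p_cells - A_g

  T_s <- tot(w1); T_v <- tot(w2)
  ss_s <- sum(T_s^2) / (v * N) - C
  ss_v <- sum(T_v^2) / (s * N) - C
  T_gs <- tot(grp, w1); T_gv <- tot(grp, w2)
  ss_ks <- sum(sweep(T_gs^2, 1, v * as.numeric(n_g), "/")) - A_g - ss_s
  ss_kv <- sum(sweep(T_gv^2, 1, s * as.numeric(n_g), "/")) - A_g - ss_v
  T_is <- tot(subj, w1); T_iv <- tot(subj, w2)
  ss_ssub <- sum(T_is^2) / v - sum(T_i^2) / p_cells - ss_s - ss_ks
  ss_vsub <- sum(T_iv^2) / s - sum(T_i^2) / p_cells - ss_v - ss_kv
  T_sv <- tot(w1, w2)
  ss_sv <- sum(T_sv^2) / N - C - ss_s - ss_v
  T_gsv <- tot(grp, w1, w2)
  ss_ksv <- sum(sweep(T_gsv^2, 1, as.numeric(n_g), "/")) - C -
    ss_k - ss_s - ss_v - ss_ks - ss_kv - ss_sv
  ss_total <- sum((y - T_all / (p_cells * N))^2)
  ss_svsub <- ss_total - (ss_k + ss_bsub + ss_s + ss_ks + ss_ssub +
                            ss_v + ss_kv + ss_vsub + ss_sv + ss_ksv)

  row <- function(effect, ss_e, df1, ss_err, df2) {
    msf <- (ss_e / df1) / (ss_err / df2)
    tibble::tibble(
      effect = effect, df1 = df1, df2 = df2, ss = ss_e, ss_error = ss_err,
      F = msf, p = stats::pf(msf, df1, df2, lower.tail = FALSE),
      partial_eta_sq = ss_e / (ss_e + ss_err)
    )
  }
  df_bsub <- N - g
  out <- list(
    row(within2, ss_v, v - 1, ss_vsub, df_bsub * (v - 1)),
    row(within1, ss_s, s - 1, ss_ssub, df_bsub * (s - 1))
  )
  if (g > 1L) {
    out <- c(out, list(
      row(between, ss_k, g - 1, ss_bsub, df_bsub),
      row(paste(between, within2, sep = ":"), ss_kv, (g - 1) * (v - 1),
          ss_vsub, df_bsub * (v - 1)),
      row(paste(between, within1, sep = ":"), ss_ks, (g - 1) * (s - 1),
          ss_ssub, df_bsub * (s - 1))
    ))
  }
  out <- c(out, list(
    row(paste(within1, within2, sep = ":"), ss_sv, (s - 1) * (v - 1),
        ss_svsub, df_bsub * (s - 1) * (v - 1))
  ))
  if (g > 1L) {
    out <- c(out, list(
      row(paste(between, within1, within2, sep = ":"), ss_ksv,
          (g - 1) * (s - 1) * (v - 1), ss_svsub,
          df_bsub * (s - 1) * (v - 1))
    ))
  }
  dplyr::bind_rows(out)
}

#' The study's 2 x 2 x 4 mixed ANOVA on bidding level
#'
#' Within-subject factors STOPPING (never-stopped vs stop-paired) and
#' VALUE (four trained levels), between-subjects factor KNOWLEDGE
#' (explicit vs implicit), dependent variable the per-cell summary in
#' `dv` (mean bidding level by default; set `dv = "bid_level_variance"`
#' for the bidding-variance variant). Reports all seven effects with F,
#' both dfs, p, and partial eta squared.
#'
#' @param cells Cell summaries from [bid_cell_summaries()] including a
#'   `knowledge` column.
#' @param dv Name of the dependent-variable column.
#' @return Effect table as in [mixed_anova()].
#' @export
mixed_anova_2x2x4 <- function(cells, dv = "mean_bid_level") {
  stopifnot(all(c("participant", "knowledge", "stopping", "value_level")
                %in% names(cells)))
  mixed_anova(cells, dv = dv, id = "participant",
              within1 = "stopping", within2 = "value_level",
              between = "knowledge")
}

#' Within-subjects 2 x 4 ANOVA (single group)
#'
#' Same machinery as [mixed_anova_2x2x4()] restricted to one group of
#' participants (e.g. the implicit learners): STOPPING and VALUE only.
#'
#' @inheritParams mixed_anova_2x2x4
#' @return Effect table with rows for VALUE, STOPPING and their
#'   interaction.
#' @export
within_anova_2x4 <- function(cells, dv = "mean_bid_level") {
  mixed_anova(cells, dv = dv, id = "participant",
              within1 = "stopping", within2 = "value_level",
              between = NULL)
}
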