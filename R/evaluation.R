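#' Area overlap ratios between a computed and a reference mask
#'
#' Computes the two overlap measures used to score a computed segmentation
#' \eqn{A_C} against a reference delineation \eqn{A_R}:
#' \deqn{AOR_1 = |A_C \cap A_R| / |A_R|, \qquad
#'       AOR_2 = |A_C \cap A_R| / |A_C \cup A_R|.}
#' AOR2 is the Jaccard index; it is symmetric in its arguments and never
#' exceeds AOR1. Both approach 1 for a perfect segmentation.
#'
#' @param mask_c Computed logical mask.
#' @param mask_r Reference logical mask (non-empty), same shape.
#' @return A one-row tibble: `area_c`, `area_r`, `intersection`, `union`,
#'   `aor1`, `aor2`.
#' @examples
#' a <- matrix(FALSE, 8, 8); a[2:5, 2:5] <- TRUE
#' overlap(a, a)
#' @export
overlap <- function(mask_c, mask_r) {
  assert_mask(mask_c, allow_empty = TRUE)
  if (!any(mask_r)) stop("empty reference mask", call. = FALSE)
  stopifnot(all(dim(mask_c) == dim(mask_r)))
  inter <- sum(mask_c & mask_r)
  uni <- sum(mask_c | mask_r)
  tibble::tibble(
    area_c = sum(mask_c), area_r = sum(mask_r),
    intersection = inter, union = uni,
    aor1 = inter / sum(mask_r), aor2 = inter / uni
  )
}

#' Agreement between two paired series of lesion areas
#'
#' Pearson's correlation and a two-sided paired Student t-test between
#' computed and reference lesion areas (pixel counts). With identical
#' series the t statistic is undefined (all differences zero); by
#' convention p = 1 is returned with a warning.
#'
#' @param areas_c,areas_r Equal-length numeric vectors (n >= 3).
#' @return A one-row tibble: `pearson_r`, `t_pvalue`, `n`.
#' @export
area_agreement <- function(areas_c, areas_r) {
  stopifnot(length(areas_c) == length(areas_r), length(areas_c) >= 3)
  if (stats::sd(areas_c) == 0 || stats::sd(areas_r) == 0)
    stop("zero-variance area series: Pearson r undefined", call. = FALSE)
  r <- stats::cor(areas_c, areas_r)
  d <- areas_c - areas_r
  p <- if (stats::sd(d) == 0) {
    warning("all paired differences are zero; reporting p = 1")
    1
  } else {
    stats::t.test(areas_c, areas_r, paired = TRUE)$p.value
  }
  tibble::tibble(pearson_r = r, t_pvalue = p, n = length(areas_c))
}

#' Batch segmentation evaluation against reference masks
#'
#' Scores the initial and refined masks of every lesion against its
#' reference mask and summarizes the batch the way segmentation studies
#' report it: per method, mean and SD of area, Pearson r and paired-t
#' p-value of areas against the reference, and mean and SD of AOR1/AOR2 —
#' plus the between-method paired t-tests on the AOR values.
#'
#' @param masks_init,masks_refined,masks_ref Lists of logical masks, equal
#'   length, shapes matching element-wise.
#' @param ids Optional lesion identifiers.
#' @return A list with `per_lesion` (tibble: one row per lesion and method),
#'   `summary` (tibble: one row per method) and `method_comparison`
#'   (tibble: paired t p-values between methods for aor1 and aor2).
#' @export
batch_evaluate <- function(masks_init, masks_refined, masks_ref,
                           ids = seq_along(masks_ref)) {
  n <- length(masks_ref)
  stopifnot(length(masks_init) == n, length(masks_refined) == n, n >= 3)
  score <- function(masks, method) {
    purrr::map2_dfr(masks, seq_len(n), function(m, i) {
      dplyr::mutate(overlap(m, masks_ref[[i]]), id = ids[i],
                    method = method, .before = 1)
    })
  }
  per_lesion <- dplyr::bind_rows(score(masks_init, "initial"),
                                 score(masks_refined, "refined"))
  ref_areas <- vapply(masks_ref, sum, 0)
  summarize_method <- function(df) {
    agr <- area_agreement(df$area_c, ref_areas)
    tibble::tibble(
      area_mean = mean(df$area_c), area_sd = stats::sd(df$area_c),
      pearson_r = agr$pearson_r, t_pvalue = agr$t_pvalue,
      aor1_mean = mean(df$aor1), aor1_sd = stats::sd(df$aor1),
      aor2_mean = mean(df$aor2), aor2_sd = stats::sd(df$aor2)
    )
  }
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_method(dplyr::filter(per_lesion, method == "initial")),
                  method = "initial", .before = 1),
    dplyr::mutate(summarize_method(dplyr::filter(per_lesion, method == "refined")),
                  method = "refined", .before = 1),
    tibble::tibble(method = "reference", area_mean = mean(ref_areas),
                   area_sd = stats::sd(ref_areas), pearson_r = NA_real_,
                   t_pvalue = NA_real_, aor1_mean = NA_real_, aor1_sd = NA_real_,
                   aor2_mean = NA_real_, aor2_sd = NA_real_)
  )
  init <- dplyr::filter(per_lesion, method == "initial")
  refd <- dplyr::filter(per_lesion, method == "refined")
  paired_p <- function(a, b) {
    if (stats::sd(a - b) == 0) {
      warning("all paired differences are zero; reporting p = 1")
      1
    } else stats::t.test(a, b, paired = TRUE)$p.value
  }
  method_comparison <- tibble::tibble(
    measure = c("aor1", "aor2"),
    p_value = c(paired_p(init$aor1, refd$aor1), paired_p(init$aor2, refd$aor2))
  )
  list(per_lesion = per_lesion, summary = summary,
       method_comparison = method_comparison)
}
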