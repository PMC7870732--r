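#' James predictive equation for lean body mass
#'
#' Sex-specific predictive equation estimating LBM from total body weight W
#' (kg) and height H (cm):
#' \deqn{male:   LBM = 1.10 W - 120 (W/H)^2}
#' \deqn{female: LBM = 1.07 W - 148 (W/H)^2}
#' This is the formula built into most clinical PET systems for SUL
#' normalisation. For extreme body habitus the quadratic term dominates and
#' the value can become implausibly low or negative; such estimates are
#' returned flagged (never silently clamped), since that pathology is
#' precisely what CT-derived LBM methods are designed to avoid.
#'
#' @param sex `"male"`/`"female"` (or `"m"`/`"f"`), recycled against the
#'   numeric inputs.
#' @param weight_kg body weight, kg (> 0).
#' @param height_cm height, cm (> 0).
#' @return A tibble with columns `method` (`"james_pe"`), `sex`, `weight_kg`,
#'   `height_cm`, `lbm_kg`, and `flagged` (TRUE when `lbm_kg` is not in
#'   `(0, weight_kg]`).
#' @export
#' @examples
#' lbm_james("male", 70, 170)$lbm_kg  # 56.654
lbm_james <- function(sex, weight_kg, height_cm) {
  sex <- norm_sex(sex)
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    abort("`weight_kg` and `height_cm` must be positive",
          class = "lbmct_domain_error")
  }
  n <- max(length(sex), length(weight_kg), length(height_cm))
  sex <- rep_len(sex, n)
  weight_kg <- rep_len(weight_kg, n)
  height_cm <- rep_len(height_cm, n)
  r2 <- (weight_kg / height_cm)^2
  lbm <- ifelse(sex == "male",
                1.10 * weight_kg - 120 * r2,
                1.07 * weight_kg - 148 * r2)
  out <- tibble(
    method = "james_pe", sex = sex,
    weight_kg = as.numeric(weight_kg), height_cm = as.numeric(height_cm),
    lbm_kg = lbm, flagged = lbm <= 0 | lbm > weight_kg
  )
  if (any(out$flagged)) {
    warn(sprintf("%d LBM estimate(s) outside (0, weight]; returned flagged",
                 sum(out$flagged)))
  }
  out
}

norm_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s == "m"] <- "male"
  s[s == "f"] <- "female"
  if (!all(s %in% c("male", "female"))) {
    abort("`sex` must be 'male'/'female' (or 'm'/'f')")
  }
  s
}

#' Linear limited-coverage fat model
#'
#' A straight-line model mapping limited-coverage fat volume FV_LC (litres)
#' to whole-body fat mass FM_WB (kg): `FM_WB = alpha + beta * FV_LC`. LBM
#' then follows by subtraction from body weight. Note the litre convention:
#' the coefficients are only dimensionally sensible with FV_LC in L, and
#' [fat_volume()] output (`fat_volume_l`) is already in those units.
#'
#' @param alpha_kg intercept, kg.
#' @param beta_kg_per_l slope, kg per litre of limited-coverage fat volume.
#' @param r Pearson correlation of the fit (optional).
#' @param n fit sample size (optional).
#' @param provenance free-text note on where the coefficients came from.
#' @return An object of class `fat_model`.
#' @seealso [fit_fat_model()], [default_fat_model()]
#' @export
fat_model <- function(alpha_kg, beta_kg_per_l, r = NA_real_, n = NA_integer_,
                      provenance = "user-supplied") {
  if (!is.finite(alpha_kg) || !is.finite(beta_kg_per_l)) {
    abort("model coefficients must be finite")
  }
  structure(
    list(alpha_kg = alpha_kg, beta_kg_per_l = beta_kg_per_l,
         r = r, n = n, provenance = provenance),
    class = "fat_model"
  )
}

#' Default published limited-coverage fat model
#'
#' Frozen coefficients of the published thorax-to-ischium equation
#' (`FM_WB = 2.892 + 1.3337 * FV_LC`, FV_LC in litres), developed on a
#' 199-patient whole-body PET/CT cohort.
#'
#' @return A `fat_model`.
#' @export
default_fat_model <- function() {
  fat_model(2.892, 1.3337, r = 0.977, n = 199L,
            provenance = "published development-cohort equation")
}

#' @export
print.fat_model <- function(x, ...) {
  cat(sprintf("<fat_model> FM_WB = %.4g + %.4g * FV_LC [kg; FV_LC in L]\n",
              x$alpha_kg, x$beta_kg_per_l))
  if (is.finite(x$r)) cat(sprintf("  Pearson r = %.4g, n = %d\n", x$r, x$n))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' Fit the limited-coverage fat model from a cohort
#'
#' Ordinary least squares of whole-body fat mass on limited-coverage fat
#' volume, with the Pearson correlation of the pair.
#'
#' @param data data frame with the fit columns.
#' @param fv,fm column names (unquoted) holding FV_LC in litres and FM_WB in
#'   kg; defaults `fv_lc_l` and `fm_wb_kg`, matching [make_cohort()] output.
#' @return A `fat_model` with `alpha_kg`, `beta_kg_per_l`, `r`, `n`, and the
#'   underlying `lm` fit in `$fit`. [tidy()] and [glance()] methods apply.
#' @export
#' @examples
#' d <- tibble::tibble(fv_lc_l = 1:10,
#'                     fm_wb_kg = 2.892 + 1.3337 * (1:10))
#' fit_fat_model(d)
fit_fat_model <- function(data, fv = fv_lc_l, fm = fm_wb_kg) {
  fv <- rlang::eval_tidy(rlang::enquo(fv), data)
  fm <- rlang::eval_tidy(rlang::enquo(fm), data)
  n <- length(fv)
  if (n < 3) abort("need at least 3 pairs to fit the fat model")
  if (sd(fv) == 0) {
    abort("degenerate fit: fat volumes have zero variance",
          class = "lbmct_fit_error")
  }
  fit <- lm(fm ~ fv)
  m <- fat_model(unname(coef(fit)[1]), unname(coef(fit)[2]),
                 r = cor(fv, fm), n = as.integer(n),
                 provenance = "fitted from cohort")
  m$fit <- fit
  m
}

#' @export
tidy.fat_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    tibble(
      term = c("alpha_kg", "beta_kg_per_l"),
      estimate = c(x$alpha_kg, x$beta_kg_per_l),
      std.error = unname(s[, "Std. Error"]),
      statistic = unname(s[, "t value"]),
      p.value = unname(s[, "Pr(>|t|)"])
    )
  } else {
    tibble(term = c("alpha_kg", "beta_kg_per_l"),
           estimate = c(x$alpha_kg, x$beta_kg_per_l))
  }
}

#' @export
glance.fat_model <- function(x, ...) {
  tibble(r = x$r, r.squared = x$r^2, n = x$n, provenance = x$provenance)
}

#' @export
predict.fat_model <- function(object, fv_lc_l, ...) {
  object$alpha_kg + object$beta_kg_per_l * fv_lc_l
}

#' Lean body mass from limited-coverage fat volume
#'
#' `LBM = W - (alpha + beta * FV_LC)`: body weight minus the whole-body fat
#' mass predicted from the limited-coverage fat volume. The conservation
#' identity `lbm_kg + fm_wb_pred_kg == weight_kg` holds exactly.
#'
#' @param weight_kg body weight, kg.
#' @param fv_lc_l limited-coverage fat volume, litres (>= 0).
#' @param model a [fat_model()]; default the published coefficients.
#' @return A tibble: `method` (`"limited_coverage"`), `weight_kg`,
#'   `fv_lc_l`, `fm_wb_pred_kg`, `lbm_kg`, `flagged`.
#' @export
#' @examples
#' lbm_lc(60, 10)$lbm_kg  # 60 - (2.892 + 13.337) = 43.771
lbm_lc <- function(weight_kg, fv_lc_l, model = default_fat_model()) {
  if (!inherits(model, "fat_model")) abort("`model` must be a `fat_model`")
  if (any(weight_kg <= 0)) {
    abort("`weight_kg` must be positive", class = "lbmct_domain_error")
  }
  if (any(fv_lc_l < 0)) {
    abort("`fv_lc_l` must be non-negative", class = "lbmct_domain_error")
  }
  fm <- model$alpha_kg + model$beta_kg_per_l * fv_lc_l
  lbm <- weight_kg - fm
  out <- tibble(
    method = "limited_coverage",
    weight_kg = as.numeric(weight_kg), fv_lc_l = as.numeric(fv_lc_l),
    fm_wb_pred_kg = fm, lbm_kg = lbm, flagged = lbm <= 0
  )
  if (any(out$flagged)) {
    warn(sprintf("%d non-positive LBM estimate(s); returned flagged",
                 sum(out$flagged)))
  }
  out
}

#' Lean body mass from whole-body CT fat mass (reference standard)
#'
#' Treats LBM as fat-free mass: `LBM_WB = W - FM_WB`, with the whole-body
#' fat mass measured directly on whole-body CT.
#'
#' @param weight_kg body weight, kg.
#' @param fm_wb_kg measured whole-body fat mass, kg; must satisfy
#'   `0 <= fm_wb_kg < weight_kg`.
#' @return A tibble: `method` (`"whole_body_reference"`), `weight_kg`,
#'   `fm_wb_kg`, `lbm_kg`.
#' @export
lbm_wholebody_reference <- function(weight_kg, fm_wb_kg) {
  if (any(weight_kg <= 0) || any(fm_wb_kg < 0)) {
    abort("weights must be positive and fat mass non-negative",
          class = "lbmct_domain_error")
  }
  if (any(fm_wb_kg >= weight_kg)) {
    abort("`fm_wb_kg` must be strictly less than `weight_kg`",
          class = "lbmct_domain_error")
  }
  tibble(
    method = "whole_body_reference",
    weight_kg = as.numeric(weight_kg), fm_wb_kg = as.numeric(fm_wb_kg),
    lbm_kg = weight_kg - fm_wb_kg
  )
}
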