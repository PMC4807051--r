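#' Thermodynamic configuration
#'
#' Gas constant and absolute temperature used to convert specificity-constant
#' ratios into free energies. Defaults match kinetic assays at 25 C with
#' energies in kcal/mol.
#'
#' @param temperature absolute temperature in kelvin.
#' @param gas_constant gas constant, kcal/(mol K).
#' @return object of class `energetics_config`.
#' @export
energetics_config <- function(temperature = 298.15, gas_constant = 1.987e-3) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("'temperature' must be positive (kelvin)")
  if (!is.numeric(gas_constant) || gas_constant <= 0)
    stop("'gas_constant' must be positive")
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 rt = gas_constant * temperature),
            class = "energetics_config")
}

#' Specificity constant kcat/KM
#'
#' The second-order rate constant kcat/KM governing competition between
#' alternative substrates for the same site; the basis of all preference and
#' binding-energy calculations in this package.
#'
#' @param value kcat/KM in 1/(uM s), positive.
#' @param se standard error, same unit (optional).
#' @param enzyme_label,cofactor_label identifying labels.
#' @return object of class `specificity_constant`.
#' @export
specificity_constant <- function(value, se = NA_real_,
                                 enzyme_label = NA_character_,
                                 cofactor_label = NA_character_) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    stop("'value' must be a single positive number")
  if (!is.na(se) && (!is.numeric(se) || se < 0))
    stop("'se' must be non-negative when present")
  structure(list(value = as.numeric(value), se = as.numeric(se),
                 enzyme_label = as.character(enzyme_label),
                 cofactor_label = as.character(cofactor_label)),
            class = "specificity_constant")
}

as_spec_constant <- function(x, ...) {
  if (inherits(x, "specificity_constant")) x
  else if (inherits(x, "mm_fit")) specificity_from_fit(x)
  else if (is.numeric(x) && length(x) == 1L) specificity_constant(x, ...)
  else stop("cannot interpret input as a specificity constant")
}

#' Specificity (preference) quotient between NADP+ and NAD+
#'
#' Ratio of one enzyme's specificity constant with NADP+ to that with NAD+.
#' The standard error is propagated to first order assuming the two constants
#' are independent (they come from fits to disjoint datasets):
#' se(q) = q * sqrt((se1/v1)^2 + (se2/v2)^2).
#'
#' @param nadp,nad `specificity_constant` objects (or bare positive numbers)
#'   for the NADP+- and NAD+-linked reactions of the same enzyme.
#' @return list with `quotient`, `se`, `enzyme_label`.
#' @export
specificity_quotient <- function(nadp, nad) {
  nadp <- as_spec_constant(nadp)
  nad <- as_spec_constant(nad)
  if (!is.na(nadp$enzyme_label) && !is.na(nad$enzyme_label) &&
      nadp$enzyme_label != nad$enzyme_label)
    stop("specificity constants belong to different enzymes: ",
         nadp$enzyme_label, " vs ", nad$enzyme_label)
  q <- nadp$value / nad$value
  se <- if (!is.na(nadp$se) && !is.na(nad$se))
    q * sqrt((nadp$se / nadp$value)^2 + (nad$se / nad$value)^2)
  else NA_real_
  list(quotient = q, se = se,
       enzyme_label = if (!is.na(nadp$enzyme_label)) nadp$enzyme_label
                      else nad$enzyme_label)
}

#' Classify cofactor preference from a specificity quotient
#'
#' Folds the NADP+/NAD+ quotient to max(q, 1/q) and assigns one of three
#' discrimination levels: below `thresholds[1]` (default 10-fold) the enzyme
#' is dual; between the two thresholds (default 10 to 100-fold, boundaries
#' included) it prefers one cofactor; above `thresholds[2]` it is specific.
#' When kcat values are unavailable, the ratio KM(NAD+)/KM(NADP+) serves as a
#' proxy for the quotient (`basis = "km_proxy"`), since in this family the
#' preference is dominated by KM differences.
#'
#' @param quotient NADP+/NAD+ specificity-constant quotient (positive), or
#'   `NULL` when classifying by KM proxy.
#' @param km_ratio KM(NAD+)/KM(NADP+) proxy (positive), used when `quotient`
#'   is `NULL`.
#' @param thresholds two increasing positive cutoffs (fold), default (10, 100).
#' @return object of class `preference_result`: `quotient`, `quotient_se`,
#'   `km_ratio`, `category` (one of `dual`, `NADP-preferring`,
#'   `NADP-specific`, `NAD-preferring`, `NAD-specific`), `preferred_cofactor`,
#'   `basis`.
#' @export
classify_preference <- function(quotient = NULL, km_ratio = NULL,
                                thresholds = c(10, 100), quotient_se = NA_real_) {
  if (length(thresholds) != 2L || any(thresholds <= 0) ||
      diff(thresholds) <= 0)
    stop("'thresholds' must be two increasing positive values")
  basis <- if (!is.null(quotient)) "specificity_constants" else "km_proxy"
  q <- if (!is.null(quotient)) quotient else km_ratio
  if (is.null(q)) stop("supply 'quotient' or 'km_ratio'")
  if (!is.numeric(q) || !is.finite(q) || q <= 0)
    stop("the quotient must be a positive number")
  fold <- max(q, 1 / q)
  level <- if (fold < thresholds[1L]) "dual"
           else if (fold <= thresholds[2L]) "preferring"
           else "specific"
  preferred <- if (q > 1) "NADP+" else if (q < 1) "NAD+" else NA_character_
  category <- if (level == "dual") "dual"
              else paste0(sub("\\+$", "", preferred), "-", level)
  structure(list(quotient = if (!is.null(quotient)) quotient else NA_real_,
                 quotient_se = quotient_se,
                 km_ratio = if (!is.null(km_ratio)) km_ratio else NA_real_,
                 category = category, preferred_cofactor = preferred,
                 basis = basis, fold = fold, thresholds = thresholds),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("Cofactor preference: %s (%.3g-fold, basis: %s)\n",
              x$category, x$fold, x$basis))
  invisible(x)
}

#' Transition-state binding energy of a group from a specificity ratio
#'
#' The binding energy that a group P (a cofactor phosphate or an amino-acid
#' side chain) contributes to the transition-state complex follows from
#' transition-state theory as RT ln of the ratio of specificity constants
#' measured without and with the group. With the quotient expressed as
#' q = (kcat/KM with P) / (kcat/KM without P), the contribution is
#' deltaG = -RT ln(q): negative (favourable) when the group improves
#' catalysis.
#'
#' @param q quotient (with P)/(without P) of specificity constants, positive.
#' @param cfg an [energetics_config()].
#' @param q_se optional standard error of `q`; propagated as
#'   se(deltaG) = RT * q_se / q.
#' @param description free-text note of which group and which pair of
#'   constants the value refers to.
#' @return object of class `delta_g`: `value` (kcal/mol), `se`,
#'   `temperature`, `description`.
#' @export
transition_state_dg <- function(q, cfg = energetics_config(), q_se = NA_real_,
                                description = NA_character_) {
  if (!is.numeric(q) || !is.finite(q) || q <= 0)
    stop("'q' must be a positive quotient of specificity constants")
  value <- -cfg$rt * log(q)
  se <- if (!is.na(q_se)) cfg$rt * q_se / q else NA_real_
  structure(list(value = value, se = se, temperature = cfg$temperature,
                 quotient = q, description = description),
            class = "delta_g")
}

#' @export
print.delta_g <- function(x, ...) {
  cat(sprintf("deltaG = %.3g%s kcal/mol (T = %.2f K)%s\n", x$value,
              if (!is.na(x$se)) sprintf(" +/- %.2g", x$se) else "",
              x$temperature,
              if (!is.na(x$description)) paste0("  [", x$description, "]")
              else ""))
  invisible(x)
}

#' Binding-energy loss on removing a side chain
#'
#' RT ln of the ratio of a parent enzyme's specificity constant to that of a
#' deletion mutant (e.g. an alanine replacement), both measured with the same
#' cofactor. Positive when the removed side chain contributed favourably to
#' transition-state binding.
#'
#' @param parent,mutant `specificity_constant` objects (or positive numbers)
#'   sharing a cofactor label.
#' @param cfg an [energetics_config()].
#' @return list with `value` (kcal/mol), `se` (propagated when both inputs
#'   carry SEs), and the labels involved.
#' @export
side_chain_removal_dg <- function(parent, mutant, cfg = energetics_config()) {
  parent <- as_spec_constant(parent)
  mutant <- as_spec_constant(mutant)
  if (!is.na(parent$cofactor_label) && !is.na(mutant$cofactor_label) &&
      parent$cofactor_label != mutant$cofactor_label)
    stop("parent and mutant were measured with different cofactors: ",
         parent$cofactor_label, " vs ", mutant$cofactor_label)
  ratio <- parent$value / mutant$value
  se <- if (!is.na(parent$se) && !is.na(mutant$se))
    cfg$rt * sqrt((parent$se / parent$value)^2 + (mutant$se / mutant$value)^2)
  else NA_real_
  list(value = cfg$rt * log(ratio), se = se,
       parent_label = parent$enzyme_label, mutant_label = mutant$enzyme_label,
       cofactor_label = parent$cofactor_label)
}

#' Double-mutant thermodynamic cycle
#'
#' Builds the 2x2 alanine-replacement cycle from four specificity constants
#' measured with one cofactor: wild type (i,j), the two single mutants (0,j)
#' and (i,0), and the double mutant (0,0). Edge energies are side-chain
#' removal losses (positive when the removed side chain was favourable):
#' \describe{
#'   \item{dg_a}{(i,j) -> (0,j): removal of side chain i with j present}
#'   \item{dg_b}{(i,j) -> (i,0): removal of side chain j with i present}
#'   \item{dg_c}{(0,j) -> (0,0): removal of j in the absence of i}
#'   \item{dg_d}{(i,0) -> (0,0): removal of i in the absence of j}
#' }
#' The coupling energy dg_d - dg_a (= dg_c - dg_b) measures how much the
#' presence of one side chain changes the contribution of the other; the
#' closure residual dg_a + dg_c - dg_b - dg_d is an algebraic identity equal
#' to zero when all four edges derive from the same four constants, and is
#' asserted to machine precision.
#'
#' @param wt,mut_a,mut_b,double `specificity_constant` objects (or positive
#'   numbers) for the four variants, all with the same cofactor. `mut_a` is
#'   the variant lacking side chain i, `mut_b` the one lacking j.
#' @param cfg an [energetics_config()].
#' @return object of class `cycle_result` with the four edges, `coupling`,
#'   `closure_residual` and the variant labels.
#' @export
build_cycle <- function(wt, mut_a, mut_b, double, cfg = energetics_config()) {
  ks <- lapply(list(wt = wt, mut_a = mut_a, mut_b = mut_b, double = double),
               as_spec_constant)
  cof <- unique(stats::na.omit(vapply(ks, `[[`, "", "cofactor_label")))
  if (length(cof) > 1L)
    stop("all four variants must share one cofactor; got: ",
         paste(cof, collapse = ", "))
  v <- vapply(ks, `[[`, 0, "value")
  rt <- cfg$rt
  dg_a <- rt * log(v[["wt"]] / v[["mut_a"]])
  dg_b <- rt * log(v[["wt"]] / v[["mut_b"]])
  dg_c <- rt * log(v[["mut_a"]] / v[["double"]])
  dg_d <- rt * log(v[["mut_b"]] / v[["double"]])
  closure <- dg_a + dg_c - dg_b - dg_d
  if (abs(closure) > 1e-9)
    stop("cycle closure violated; the four constants are inconsistent")
  structure(list(labels = vapply(ks, `[[`, "", "enzyme_label"),
                 cofactor_label = if (length(cof)) cof else NA_character_,
                 dg_a = dg_a, dg_b = dg_b, dg_c = dg_c, dg_d = dg_d,
                 coupling = dg_d - dg_a,
                 closure_residual = closure,
                 temperature = cfg$temperature),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, digits = 3, ...) {
  lb <- x$labels
  f <- function(z) format(z, digits = digits)
  cat("Double-mutant cycle (", x$cofactor_label, ")\n", sep = "")
  cat(sprintf("  (i,j) %s --a: %s--> (0,j) %s\n", lb[["wt"]], f(x$dg_a),
              lb[["mut_a"]]))
  cat(sprintf("  (i,j) %s --b: %s--> (i,0) %s\n", lb[["wt"]], f(x$dg_b),
              lb[["mut_b"]]))
  cat(sprintf("  (0,j) %s --c: %s--> (0,0) %s\n", lb[["mut_a"]], f(x$dg_c),
              lb[["double"]]))
  cat(sprintf("  (i,0) %s --d: %s--> (0,0) %s\n", lb[["mut_b"]], f(x$dg_d),
              lb[["double"]]))
  cat(sprintf("  coupling = %s kcal/mol; closure residual = %.2e\n",
              f(x$coupling), x$closure_residual))
  invisible(x)
}

#' Contribution of the 2'-phosphate to transition-state binding
#'
#' Composes [specificity_quotient()] and [transition_state_dg()]: the group P
#' is the 2'-phosphate, the only chemical difference between NADP+ and NAD+,
#' so its transition-state binding energy for one enzyme is -RT ln of the
#' NADP+/NAD+ quotient of specificity constants. Negative values mean the
#' phosphate is recognised favourably.
#'
#' @param nadp,nad `specificity_constant` objects for the two cofactors.
#' @param cfg an [energetics_config()].
#' @return a `delta_g` object (see [transition_state_dg()]).
#' @export
phosphate_contribution <- function(nadp, nad, cfg = energetics_config()) {
  q <- specificity_quotient(nadp, nad)
  transition_state_dg(q$quotient, cfg, q_se = q$se,
                      description = paste0("2'-phosphate, ", q$enzyme_label))
}
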