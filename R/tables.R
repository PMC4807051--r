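#' Published kinetic parameters of E. coli G6PDH variants
#'
#' Apparent Michaelis-Menten parameters for the NADP+- and NAD+-linked
#' reactions of wild-type glucose-6-phosphate dehydrogenase from E. coli and
#' its 2'-phosphate-pocket mutants (K18A, R50A, the K18A-R50A double mutant,
#' and K18T), as determined from hyperbolic fits of initial-rate data at
#' near-saturating glucose-6-phosphate. Values are the printed table entries
#' (plus/minus one standard error); the `kcat_over_km` column is the printed
#' specificity constant, which is rounded independently of `km` and `kcat`
#' and is the column preference quotients are computed from.
#'
#' @return data.frame with columns `enzyme`, `cofactor`, `km` (uM), `km_se`,
#'   `kcat` (1/s), `kcat_se`, `kcat_over_km` (1/(uM s)), `kcat_over_km_se`.
#' @seealso [bacterial_g6pdh_kinetics()], [variant_specificity()]
#' @export
ecoli_g6pdh_kinetics <- function() {
  df <- rbind(
    data.frame(enzyme = "WT",        cofactor = "NADP+", km = 7.5,   km_se = 0.8,  kcat = 174, kcat_se = 2,  kcat_over_km = 23.2,  kcat_over_km_se = 2.4),
    data.frame(enzyme = "WT",        cofactor = "NAD+",  km = 5090,  km_se = 400,  kcat = 288, kcat_se = 5,  kcat_over_km = 0.06,  kcat_over_km_se = 4e-3),
    data.frame(enzyme = "K18A",      cofactor = "NADP+", km = 99,    km_se = 3,    kcat = 143, kcat_se = 1,  kcat_over_km = 1.4,   kcat_over_km_se = 0.04),
    data.frame(enzyme = "K18A",      cofactor = "NAD+",  km = 2477,  km_se = 260,  kcat = 109, kcat_se = 2,  kcat_over_km = 0.04,  kcat_over_km_se = 4e-3),
    data.frame(enzyme = "R50A",      cofactor = "NADP+", km = 382,   km_se = 48,   kcat = 189, kcat_se = 5,  kcat_over_km = 0.5,   kcat_over_km_se = 0.06),
    data.frame(enzyme = "R50A",      cofactor = "NAD+",  km = 14662, km_se = 2176, kcat = 171, kcat_se = 10, kcat_over_km = 0.01,  kcat_over_km_se = 1e-3),
    data.frame(enzyme = "K18A-R50A", cofactor = "NADP+", km = 17696, km_se = 1453, kcat = 185, kcat_se = 7,  kcat_over_km = 0.01,  kcat_over_km_se = 9e-4),
    data.frame(enzyme = "K18A-R50A", cofactor = "NAD+",  km = 11736, km_se = 804,  kcat = 165, kcat_se = 4,  kcat_over_km = 0.01,  kcat_over_km_se = 7e-4),
    data.frame(enzyme = "K18T",      cofactor = "NADP+", km = 243,   km_se = 5.3,  kcat = 282, kcat_se = 1,  kcat_over_km = 1.1,   kcat_over_km_se = 0.03),
    data.frame(enzyme = "K18T",      cofactor = "NAD+",  km = 8352,  km_se = 307,  kcat = 298, kcat_se = 4,  kcat_over_km = 0.03,  kcat_over_km_se = 1e-3))
  df
}

#' Specificity constant of one variant/cofactor from the packaged table
#'
#' @param enzyme variant label in [ecoli_g6pdh_kinetics()].
#' @param cofactor `"NADP+"` or `"NAD+"`.
#' @return a [specificity_constant()] built from the printed kcat/KM column.
#' @export
variant_specificity <- function(enzyme, cofactor) {
  tab <- ecoli_g6pdh_kinetics()
  row <- tab[tab$enzyme == enzyme & tab$cofactor == cofactor, ]
  if (nrow(row) != 1L)
    stop("no table entry for ", enzyme, " / ", cofactor)
  specificity_constant(row$kcat_over_km, se = row$kcat_over_km_se,
                       enzyme_label = enzyme, cofactor_label = cofactor)
}

#' Published kinetic parameters of bacterial G6PDHs
#'
#' Literature survey of bacterial glucose-6-phosphate dehydrogenases with
#' cofactor kinetics characterised for both NADP+ and NAD+. Where kcat was
#' not reported the entry is `NA` and the preference must be judged by the
#' KM ratio proxy. Units: KM in uM, kcat in 1/s.
#'
#' @return data.frame with columns `organism`, `km_nadp`, `kcat_nadp`,
#'   `km_nad`, `kcat_nad`.
#' @seealso [classify_bacterial_g6pdh()]
#' @export
bacterial_g6pdh_kinetics <- function() {
  df <- rbind(
    data.frame(organism = "Gluconacetobacter hansenii", km_nadp = 340, kcat_nadp = 1288,  km_nad = 104,   kcat_nad = 2133),
    data.frame(organism = "Pseudomonas fluorescens",    km_nadp = 360, kcat_nadp = 1117,  km_nad = 150,   kcat_nad = 1383),
    data.frame(organism = "Azotobacter vinelandii",     km_nadp = 50,  kcat_nadp = 37,    km_nad = 220,   kcat_nad = 92),
    data.frame(organism = "Zymomonas mobilis",          km_nadp = 40,  kcat_nadp = 338,   km_nad = 210,   kcat_nad = 589),
    data.frame(organism = "Streptomyces aureofaciens",  km_nadp = 75,  kcat_nadp = NA,    km_nad = 140,   kcat_nad = NA),
    data.frame(organism = "Aquifex aeolicus",           km_nadp = 161, kcat_nadp = 894,   km_nad = 2096,  kcat_nad = 2012),
    data.frame(organism = "Leuconostoc mesenteroides",  km_nadp = 8,   kcat_nadp = 522,   km_nad = 162,   kcat_nad = 1125),
    data.frame(organism = "Burkholderia multivorans",   km_nadp = 40,  kcat_nadp = NA,    km_nad = 500,   kcat_nad = NA),
    data.frame(organism = "Pseudomonas aeruginosa",     km_nadp = 57,  kcat_nadp = NA,    km_nad = 333,   kcat_nad = NA),
    data.frame(organism = "Methylomonas",               km_nadp = 14,  kcat_nadp = NA,    km_nad = 200,   kcat_nad = NA),
    data.frame(organism = "Gluconobacter oxydans",      km_nadp = 26,  kcat_nadp = 43,    km_nad = 740,   kcat_nad = 43),
    data.frame(organism = "Burkholderia cepacia",       km_nadp = 20,  kcat_nadp = NA,    km_nad = 1800,  kcat_nad = NA),
    data.frame(organism = "Escherichia coli",           km_nadp = 8,   kcat_nadp = 178,   km_nad = 5224,  kcat_nad = 280),
    data.frame(organism = "Bacillus licheniformis",     km_nadp = 5,   kcat_nadp = NA,    km_nad = 3000,  kcat_nad = NA),
    data.frame(organism = "Thermotoga maritima",        km_nadp = 40,  kcat_nadp = 35000, km_nad = 12000, kcat_nad = 11000))
  df
}

#' Classify the cofactor preference of the surveyed bacterial G6PDHs
#'
#' For each organism in [bacterial_g6pdh_kinetics()], computes the NADP+/NAD+
#' specificity quotient from the KM and kcat columns when both kcat values
#' are available, otherwise falls back to the KM(NAD+)/KM(NADP+) proxy, and
#' applies [classify_preference()].
#'
#' @param thresholds passed to [classify_preference()].
#' @return data.frame with `organism`, `quotient`, `km_ratio`, `basis`,
#'   `category`.
#' @export
classify_bacterial_g6pdh <- function(thresholds = c(10, 100)) {
  tab <- bacterial_g6pdh_kinetics()
  res <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    km_ratio <- r$km_nad / r$km_nadp
    if (!is.na(r$kcat_nadp) && !is.na(r$kcat_nad)) {
      q <- (r$kcat_nadp / r$km_nadp) / (r$kcat_nad / r$km_nad)
      cl <- classify_preference(quotient = q, thresholds = thresholds)
    } else {
      q <- NA_real_
      cl <- classify_preference(km_ratio = km_ratio, thresholds = thresholds)
    }
    data.frame(organism = r$organism, quotient = q, km_ratio = km_ratio,
               basis = cl$basis, category = cl$category)
  })
  do.call(rbind, res)
}
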