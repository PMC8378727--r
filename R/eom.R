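#' Van Soest quality of an exogenous organic matter (EOM)
#'
#' Describes an organic amendment (ruminant excreta, slurry, manure) by its
#' Van Soest fibre fractions, each as percent of volatile solids (VS).
#' The three fractions must sum to 100 (+/- 1).
#'
#' @param lignin,holocellulose,solubles fractions, percent of VS
#' @param label free-text label for reporting
#' @return an object of class `eom_quality`
#' @export
eom_quality <- function(lignin, holocellulose, solubles,
                        label = "unnamed EOM") {
  fr <- c(lignin = lignin, holocellulose = holocellulose,
          solubles = solubles)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 100))
    stop("eom_quality: fractions must be in [0, 100]")
  if (abs(sum(fr) - 100) > 1)
    stop("eom_quality: fractions must sum to ~100% of VS (got ",
         round(sum(fr), 2), ")")
  structure(list(lignin = lignin, holocellulose = holocellulose,
                 solubles = solubles, label = label),
            class = "eom_quality")
}

#' Shipped default ruminant excreta quality
#'
#' Lignin 18.5% VS — the midpoint of the 9–28% literature interval used for
#' sensitivity analysis — with the remainder split between holocellulose
#' and solubles. With [partition_eom()] this quality reproduces the
#' canonical ruminant entry-pool partition 0.1 / 0.6 / 0.3
#' (HUM / RPM / DPM) at one-decimal rounding. A default, not an assertion:
#' override per application when measured fractions are available.
#'
#' @return an `eom_quality`
#' @export
ruminant_excreta_quality <- function() {
  eom_quality(lignin = 18.5, holocellulose = 45, solubles = 36.5,
              label = "ruminant excreta (literature default)")
}

#' Anaerobic biodegradability from lignin content
#'
#' B = 0.905 exp(-0.055 lignin), with lignin as percent of volatile
#' solids. Strictly decreasing; B in (0, 0.905].
#'
#' @param lignin lignin content, percent of VS, in \[0, 100\] (vectorised)
#' @return dimensionless biodegradability
#' @export
biodegradability <- function(lignin) {
  if (any(!is.finite(lignin)) || any(lignin < 0) || any(lignin > 100))
    stop("biodegradability: lignin must be in [0, 100]")
  0.905 * exp(-0.055 * lignin)
}

#' Partition EOM carbon into HUM/RPM/DPM entry pools
#'
#' Maps Van Soest fractions to the model's entry pools through the
#' biodegradability B: the non-degradable part of lignin enters HUM; the
#' degradable lignin plus the non-degradable part of holocellulose and
#' solubles enter RPM; the degradable part of holocellulose and solubles
#' enters DPM. Fractions are normalised by total VS so they sum to 1.
#'
#' @param q an [eom_quality()]
#' @return an object of class `eom_partition`: `f_hum`, `f_rpm`, `f_dpm`
#'   (fractions of applied C, summing to 1)
#' @export
partition_eom <- function(q) {
  stopifnot(inherits(q, "eom_quality"))
  B <- biodegradability(q$lignin)
  hs <- q$holocellulose + q$solubles
  tot <- q$lignin + hs
  f_hum <- q$lignin * (1 - B) / tot
  f_rpm <- (q$lignin * B + hs * (1 - B)) / tot
  f_dpm <- hs * B / tot
  structure(list(f_hum = f_hum, f_rpm = f_rpm, f_dpm = f_dpm,
                 label = q$label),
            class = "eom_partition")
}

#' Reference-model farmyard manure split
#'
#' The fixed entry split the unmodified model applies to all organic
#' amendments: DPM 49%, RPM 49%, HUM 2%. Used when the excreta-quality
#' modification is off, so the version ladder is well defined.
#'
#' @return an `eom_partition`
#' @export
fym_partition <- function() {
  structure(list(f_hum = 0.02, f_rpm = 0.49, f_dpm = 0.49,
                 label = "farmyard manure (reference split)"),
            class = "eom_partition")
}

#' Monthly entry-pool additions from a schedule of EOM applications
#'
#' @param applications list of applications, each a list with `month`
#'   (1-12), `c_amount` (Mg C ha\eqn{^{-1}}) and either `quality` (an
#'   [eom_quality()]) or `partition` (an `eom_partition`); applications
#'   without either use `default_partition`
#' @param default_partition entry split for applications that do not carry
#'   their own quality (default: the ruminant literature quality)
#' @return 12 x 3 matrix (rows = months, columns `dpm`, `rpm`, `hum`) of C
#'   additions, Mg C ha\eqn{^{-1}}
#' @export
eom_monthly_inputs <- function(applications,
                               default_partition =
                                 partition_eom(ruminant_excreta_quality())) {
  out <- matrix(0, nrow = 12, ncol = 3,
                dimnames = list(NULL, c("dpm", "rpm", "hum")))
  for (app in applications) {
    m <- app$month
    if (is.null(m) || !(m %in% 1:12))
      stop("eom_monthly_inputs: application month must be in 1..12")
    amt <- app$c_amount
    if (!is.finite(amt) || amt < 0)
      stop("eom_monthly_inputs: c_amount must be >= 0")
    p <- if (!is.null(app$partition)) app$partition
         else if (!is.null(app$quality)) partition_eom(app$quality)
         else default_partition
    out[m, "dpm"] <- out[m, "dpm"] + amt * p$f_dpm
    out[m, "rpm"] <- out[m, "rpm"] + amt * p$f_rpm
    out[m, "hum"] <- out[m, "hum"] + amt * p$f_hum
  }
  out
}
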