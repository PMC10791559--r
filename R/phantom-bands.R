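# Synthetic immunoblot band-intensity tables with known true ratios.

#' Generate a synthetic band-intensity table
#'
#' Builds a long-format densitometry table for one of the three immunoblot
#' quantification schemes, with per-lane multiplicative log-normal noise of a
#' given coefficient of variation and loading-control (Coomassie blue, CB)
#' intensities included.
#'
#' Schemes:
#' * `"pka_con"` -- WCL lanes for CON and PKA per experiment; the true
#'   PKA:CON band-intensity ratio is `trueRatios[target]`.
#' * `"coip"` -- WCL and `IP_pos` lanes per condition; the degree of
#'   coimmunoprecipitation `IP_pos/WCL` has a PKA:CON ratio equal to the
#'   truth.
#' * `"surface"` -- as `"coip"` with `biotinylated` lanes (surface fraction).
#'
#' @param trueRatios named numeric vector: true PKA:CON ratio per target
#'   protein; all values must be positive.
#' @param laneNoiseCv per-lane log-normal noise coefficient of variation
#'   (0 = exact recovery).
#' @param seed integer RNG seed.
#' @param scheme one of `"pka_con"`, `"coip"`, `"surface"`.
#' @param nExperiments number of independent experiments to emulate.
#' @param baseIntensity arbitrary base band intensity of a CON WCL lane.
#' @param baseDegree true CON-condition pulldown/WCL degree (schemes
#'   `"coip"`/`"surface"`).
#' @return `data.frame` with columns `experimentId`, `condition`
#'   (`CON`/`PKA`), `laneKind` (`WCL`, `IP_pos`, `biotinylated`), `target`,
#'   `bandIntensity`, `cbIntensity`.
#' @seealso [ratioPkaCon()], [coipDegree()], [surfaceDegree()]
#' @export
makeBandTable <- function(trueRatios, laneNoiseCv = 0, seed = 1L,
                          scheme = c("pka_con", "coip", "surface"),
                          nExperiments = 5L, baseIntensity = 100,
                          baseDegree = 2) {
  scheme <- match.arg(scheme)
  if (is.null(names(trueRatios)) || any(!nzchar(names(trueRatios)))) {
    stop("trueRatios must be a named vector (one name per target protein)")
  }
  if (any(trueRatios <= 0)) stop("true ratios must be positive")
  if (laneNoiseCv < 0) stop("laneNoiseCv must be >= 0")

  sdlog <- sqrt(log(1 + laneNoiseCv^2))
  noise <- function(k) {
    if (laneNoiseCv == 0) rep(1, k) else exp(stats::rnorm(k, 0, sdlog))
  }
  pull <- switch(scheme, coip = "IP_pos", surface = "biotinylated", NA)

  withSeed(seed, {
    rows <- list()
    for (ex in seq_len(nExperiments)) {
      for (tg in names(trueRatios)) {
        r <- trueRatios[[tg]]
        if (scheme == "pka_con") {
          lanes <- data.frame(
            condition = c("CON", "PKA"), laneKind = "WCL",
            bandIntensity = baseIntensity * c(1, r) * noise(2),
            cbIntensity = baseIntensity * noise(2)
          )
        } else {
          # WCL equal across conditions; pulldown carries the degree
          lanes <- data.frame(
            condition = rep(c("CON", "PKA"), each = 2),
            laneKind = rep(c("WCL", pull), 2),
            bandIntensity = baseIntensity *
              c(1, baseDegree, 1, baseDegree * r) * noise(4),
            cbIntensity = baseIntensity * noise(4)
          )
        }
        lanes$experimentId <- ex
        lanes$target <- tg
        rows[[length(rows) + 1L]] <- lanes
      }
    }
    out <- do.call(rbind, rows)
    out[, c("experimentId", "condition", "laneKind", "target",
            "bandIntensity", "cbIntensity")]
  })
}
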