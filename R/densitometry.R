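# Immunoblot densitometry ratio schemes with per-experiment pairing.

checkBandTable <- function(table) {
  need <- c("experimentId", "condition", "laneKind", "target",
            "bandIntensity")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("band table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(table$bandIntensity < 0)) stop("band intensities must be >= 0")
  invisible(table)
}

bandValue <- function(table, ex, cond, kind, target, cb = FALSE) {
  sel <- table$experimentId == ex & table$condition == cond &
    table$laneKind == kind & table$target == target
  if (!any(sel)) return(NA_real_)
  v <- table$bandIntensity[sel][1]
  if (cb) {
    cbv <- table$cbIntensity[sel][1]
    if (is.na(cbv) || cbv <= 0) return(NA_real_)
    v <- v / cbv
  }
  v
}

summarizeRatios <- function(per, valueCol = "ratio") {
  ok <- per[[valueCol]][!is.na(per[[valueCol]])]
  if (!length(ok)) {
    return(data.frame(n = 0L, mean = NA_real_, se = NA_real_,
                      pVsOne = NA_real_))
  }
  p <- if (length(ok) >= 2L && stats::sd(ok) > 0) {
    stats::t.test(ok, mu = 1)$p.value
  } else NA_real_
  data.frame(n = length(ok), mean = mean(ok),
             se = if (length(ok) >= 2L) se(ok) else NA_real_,
             pVsOne = p)
}

#' PKA:CON ratio of band intensities
#'
#' For each experiment with both conditions present, the ratio of PKA to CON
#' band intensity of the target protein in the same kind of lane, optionally
#' corrected by the Coomassie-blue loading stain
#' (`(I_PKA/CB_PKA) / (I_CON/CB_CON)`). Experiments lacking a lane or with a
#' zero denominator are retained in the output with an `NA` ratio and a
#' reason -- exclusions are never silent.
#'
#' @param table band table (see [makeBandTable()] for the schema).
#' @param target target protein name.
#' @param useCb apply the Coomassie-blue loading correction.
#' @param laneKind which lane kind to ratio (default `"WCL"`).
#' @return list with `perExperiment` (`experimentId`, `ratio`, `reason`) and
#'   `summary` (`n`, `mean`, `se`, `pVsOne` from a one-sample t test
#'   against 1).
#' @export
ratioPkaCon <- function(table, target, useCb = FALSE, laneKind = "WCL") {
  checkBandTable(table)
  exs <- sort(unique(table$experimentId[table$target == target]))
  if (!length(exs)) stop("no experiments with target '", target, "'")
  per <- do.call(rbind, lapply(exs, function(ex) {
    iCon <- bandValue(table, ex, "CON", laneKind, target, cb = useCb)
    iPka <- bandValue(table, ex, "PKA", laneKind, target, cb = useCb)
    if (is.na(iCon) || is.na(iPka)) {
      return(data.frame(experimentId = ex, ratio = NA_real_,
                        reason = "missing lane"))
    }
    if (iCon == 0) {
      return(data.frame(experimentId = ex, ratio = NA_real_,
                        reason = "zero CON denominator"))
    }
    data.frame(experimentId = ex, ratio = iPka / iCon, reason = "")
  }))
  dropped <- per$experimentId[is.na(per$ratio)]
  if (length(dropped)) {
    message("ratioPkaCon: experiment(s) excluded: ",
            paste(dropped, collapse = ", "))
  }
  list(perExperiment = per, summary = summarizeRatios(per))
}

degreeScheme <- function(table, target, pullKind, absolute, loadingRatio) {
  checkBandTable(table)
  exs <- sort(unique(table$experimentId[table$target == target]))
  if (!length(exs)) stop("no experiments with target '", target, "'")
  per <- do.call(rbind, lapply(exs, function(ex) {
    row <- data.frame(experimentId = ex, degreeCon = NA_real_,
                      degreePka = NA_real_, effect = NA_real_, reason = "")
    for (cond in c("CON", "PKA")) {
      wcl <- bandValue(table, ex, cond, "WCL", target)
      pull <- bandValue(table, ex, cond, pullKind, target)
      if (is.na(wcl) || is.na(pull)) {
        row$reason <- paste0("missing ", cond, " lane")
        next
      }
      if (wcl == 0) {
        row$reason <- paste0("zero ", cond, " WCL")
        next
      }
      d <- pull / wcl
      if (absolute) d <- d / loadingRatio
      if (cond == "CON") row$degreeCon <- d else row$degreePka <- d
    }
    if (!is.na(row$degreeCon) && !is.na(row$degreePka)) {
      if (row$degreeCon == 0) {
        row$reason <- "zero CON degree"
      } else {
        row$effect <- row$degreePka / row$degreeCon
      }
    }
    row
  }))
  dropped <- per$experimentId[is.na(per$effect)]
  if (length(dropped)) {
    message(pullKind, " degree: experiment(s) excluded: ",
            paste(dropped, collapse = ", "))
  }
  list(perExperiment = per, summary = summarizeRatios(per, "effect"))
}

#' Degree of coimmunoprecipitation and its PKA:CON effect
#'
#' Per experiment and condition, the `[+] IP / WCL` band-intensity ratio of
#' the target in the same experiment is the degree of
#' coimmunoprecipitation; the effect of kinase activation is the PKA:CON
#' ratio of these degrees. Lanes are loaded at a fixed WCL : pulldown
#' equivalent of 1:`loadingRatio` (the acquisition convention is 1:20), so
#' raw degrees overstate absolute recovery by that factor; `absolute = TRUE`
#' applies it.
#'
#' @param table band table with `WCL` and `IP_pos` lanes.
#' @param target target protein name.
#' @param absolute divide degrees by the loading ratio.
#' @param loadingRatio WCL : pulldown-equivalent loading ratio.
#' @return list with `perExperiment` (`degreeCon`, `degreePka`, `effect`)
#'   and `summary` of the effect.
#' @export
coipDegree <- function(table, target, absolute = FALSE, loadingRatio = 20) {
  degreeScheme(table, target, "IP_pos", absolute, loadingRatio)
}

#' Degree of surface biotinylation and its PKA:CON effect
#'
#' As [coipDegree()] with the `biotinylated` (cell-surface) fraction:
#' `biotinylated / WCL` is the degree of protein biotinylation, and its
#' PKA:CON ratio measures the change in surface expression.
#'
#' @inheritParams coipDegree
#' @export
surfaceDegree <- function(table, target, absolute = FALSE,
                          loadingRatio = 20) {
  degreeScheme(table, target, "biotinylated", absolute, loadingRatio)
}
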