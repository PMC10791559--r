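# End-to-end phantom-cohort pipeline: generate CON/PKA cohorts, run the
# measurement stages, and summarize groups.

knownStages <- c("phantom", "enrich", "clusters", "report")

#' Assemble a pipeline run configuration
#'
#' @param seed master seed; every per-cell seed is derived from it.
#' @param stages stages to run, in dependency order; subset of
#'   `"phantom"`, `"enrich"`, `"clusters"`, `"report"`.
#' @param nCon,nPka number of cells per group.
#' @param base named list of [phantomSpec()] overrides shared by both
#'   groups.
#' @param con,pka per-group [phantomSpec()] overrides (e.g. differing
#'   `lateralEnrichment`).
#' @param outDir optional output directory for CSV tables and the JSON
#'   provenance record.
#' @return a `RunConfig` list.
#' @seealso [runPipeline()]
#' @export
runConfig <- function(seed = 1L, stages = c("phantom", "enrich", "report"),
                      nCon = 10L, nPka = 10L, base = list(),
                      con = list(), pka = list(), outDir = NULL) {
  if (!length(stages)) stop("at least one stage must be requested")
  bad <- setdiff(stages, knownStages)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(knownStages, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), stages = stages,
                 nCon = as.integer(nCon), nPka = as.integer(nPka),
                 base = base, con = con, pka = pka, outDir = outDir),
            class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [runConfig()] arguments.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y[intersect(names(y), names(formals(runConfig)))])
}

cellSpec <- function(config, group, i) {
  overrides <- utils::modifyList(config$base,
                                 if (group == "PKA") config$pka else config$con)
  offset <- if (group == "PKA") 500000L else 0L
  overrides$seed <- (config$seed * 7919L + offset + i) %% .Machine$integer.max
  do.call(phantomSpec, overrides)
}

measureCell <- function(config, group, i) {
  spec <- cellSpec(config, group, i)
  ph <- makeMyocyteStack(spec)
  tr <- ph$truth
  plane <- getChannel(ph$stack, "target")[, , tr$centralZ]
  bg <- estimateBackground(plane, tr$bgMask, tr$cellMask)
  row <- data.frame(group = group, cell = i, seed = spec$seed,
                    background = bg)
  if ("enrich" %in% config$stages) {
    lat <- lateralEnrichment(plane, tr$cellMask, tr$rimMask, background = bg)
    icd <- icdEnrichment(plane, tr$cellMask, tr$icdMask, background = bg)
    row$lateralEnrichment <- lat$enrichment
    row$icdEnrichment <- if (is.list(icd)) icd$enrichment else NA_real_
    row$pixelContent <- lat$pixelContentTotal
  }
  if ("clusters" %in% config$stages) {
    surf <- getChannel(ph$stack, "target")[, , tr$surfaceZ]
    cs <- segmentClusters(surf, tr$cellMask)
    st <- clusterStats(cs, background = bg)
    row$clusterDensityPct <- st$densityPct
    row$clusterMeanSizeUm2 <- st$meanSizeUm2
    row$nClusters <- st$nClusters
  }
  row
}

#' Run the phantom-cohort pipeline
#'
#' Generates a CON and a PKA phantom cohort, runs the requested measurement
#' stages on every cell, and reports group summaries plus PKA:CON ratios of
#' the group means. Fully deterministic for a fixed configuration and seed.
#'
#' @param config a [runConfig()] (or a list acceptable to it).
#' @return a `CohortReport` list: `perCell` (one row per cell), `summary`
#'   (per metric and group), `groupRatios` (named PKA:CON ratios of group
#'   means), `provenance` (the exact configuration and package version).
#' @examples
#' \donttest{
#' cfg <- runConfig(seed = 7, nCon = 2, nPka = 2,
#'                  base = list(cellLengthUm = 30, cellWidthUm = 12,
#'                              cellHeightUm = 0.9, applyPsf = FALSE,
#'                              applyNoise = FALSE),
#'                  con = list(lateralEnrichment = 1.5),
#'                  pka = list(lateralEnrichment = 3))
#' runPipeline(cfg)
#' }
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- do.call(runConfig, config)
  if (!"phantom" %in% config$stages) {
    stop("this pipeline runs on phantom cohorts; include the 'phantom' stage")
  }
  rows <- list()
  for (i in seq_len(config$nCon)) {
    rows[[length(rows) + 1L]] <- measureCell(config, "CON", i)
  }
  for (i in seq_len(config$nPka)) {
    rows[[length(rows) + 1L]] <- measureCell(config, "PKA", i)
  }
  perCell <- do.call(rbind, rows)

  metrics <- setdiff(names(perCell), c("group", "cell", "seed"))
  summary <- NULL
  ratios <- numeric(0)
  if ("report" %in% config$stages) {
    summary <- do.call(rbind, lapply(metrics, function(m) {
      s <- summarizeGroups(perCell, valueCol = m)
      s$metric <- m
      s
    }))
    for (m in metrics) {
      mc <- mean(perCell[[m]][perCell$group == "CON"], na.rm = TRUE)
      mp <- mean(perCell[[m]][perCell$group == "PKA"], na.rm = TRUE)
      ratios[[m]] <- mp / mc
    }
  }
  prov <- list(config = unclass(config),
               package = as.character(utils::packageVersion("myoquant")))
  report <- structure(list(perCell = perCell, summary = summary,
                           groupRatios = ratios, provenance = prov),
                      class = "CohortReport")
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(perCell, file.path(config$outDir, "per_cell.csv"),
                     row.names = FALSE)
    if (!is.null(summary)) {
      utils::write.csv(summary, file.path(config$outDir, "summary.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(prov, file.path(config$outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("CohortReport:", nrow(x$perCell), "cells (",
      sum(x$perCell$group == "CON"), "CON /",
      sum(x$perCell$group == "PKA"), "PKA )\n")
  if (length(x$groupRatios)) {
    cat("  PKA:CON ratios of group means:\n")
    for (m in names(x$groupRatios)) {
      cat(sprintf("    %-22s %.4g\n", m, x$groupRatios[[m]]))
    }
  }
  invisible(x)
}

#' Group summary statistics for a per-cell metric table
#'
#' Mean, standard error, median and quartiles per group, plus a Welch t test
#' between the groups when exactly two are present (reporting convenience).
#' Singleton groups are summarized without an SE and flagged.
#'
#' @param perCell `data.frame` with a grouping column and the metric.
#' @param valueCol metric column name.
#' @param groupCol grouping column name.
#' @return `data.frame`, one row per group, with a `welchP` attribute when
#'   applicable.
#' @examples
#' df <- data.frame(group = rep(c("CON", "PKA"), each = 3),
#'                  v = c(1, 2, 3, 2, 4, 6))
#' summarizeGroups(df, "v")
#' @export
summarizeGroups <- function(perCell, valueCol, groupCol = "group") {
  groups <- unique(perCell[[groupCol]])
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- perCell[[valueCol]][perCell[[groupCol]] == g]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), mean = mean(v),
               se = if (length(v) >= 2L) se(v) else NA_real_,
               median = q[2], q25 = q[1], q75 = q[3],
               singleton = length(v) < 2L)
  }))
  if (any(out$singleton)) {
    warning("singleton group(s): SE not defined for ",
            paste(out$group[out$singleton], collapse = ", "))
  }
  if (length(groups) == 2L && all(out$n >= 2L)) {
    v1 <- perCell[[valueCol]][perCell[[groupCol]] == groups[1]]
    v2 <- perCell[[valueCol]][perCell[[groupCol]] == groups[2]]
    # degenerate (constant) data carries no test information
    attr(out, "welchP") <- tryCatch(stats::t.test(v1, v2)$p.value,
                                    error = function(e) NA_real_)
  }
  out
}
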