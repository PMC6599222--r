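#' Run the full agreement-validation pipeline
#'
#' Reproduces the complete analysis flow on any dataset in the supported
#' formats: per-expert repeatability (IRC), pairwise similarity matrices
#' for the requested metrics, Williams' index per rater (the automated
#' method joins through the diffZ matrix), leave-one-out WI for the
#' method, the leave-one-out artificial-ground-truth power analysis, and
#' the interval/region displacement tables.  Results are written as tidy
#' CSVs plus a machine-readable JSON summary; reruns with the same inputs
#' are bit-identical (the pipeline itself draws no random numbers).
#'
#' @param segmentations named list of \code{\link{SegmentationSet}}s, or a
#'   path to a long-form segmentation CSV.
#' @param methodDisplacements the method's
#'   \code{\link{DisplacementFieldSet}}, or a path to a displacement CSV
#'   (rater id \code{"method"}).
#' @param geometry a \code{\link{ScanGeometry}} (required when paths are
#'   given).
#' @param scanInfo optional data.frame (or CSV path) with \code{scan_id},
#'   \code{interval_months}, \code{eye} for the reporting tables.
#' @param toleranceUm IRC tolerance l (default 20 um).
#' @param alpha significance level (default 0.01).
#' @param metrics similarity metrics for the Williams' index.
#' @param ttestMode \code{"absolute"} or \code{"signed"}.
#' @param outDir output directory for CSV/JSON reports, or NULL to skip
#'   writing.
#' @return An \code{agreementReport} list: \code{irc} data.frame,
#'   \code{similarity} (list of \code{\link{SimilarityMatrix}}),
#'   \code{wi} data.frame (rater x metric), \code{methodLOO},
#'   \code{power} (a \code{\link{powerSummary}}), \code{params}.
#' @export
runPipeline <- function(segmentations, methodDisplacements = NULL,
                        geometry = NULL, scanInfo = NULL,
                        toleranceUm = 20, alpha = 0.01,
                        metrics = c("diffZ", "BLD", "DC", "JC"),
                        ttestMode = c("absolute", "signed"),
                        outDir = NULL) {
    ttestMode <- match.arg(ttestMode)
    metrics <- match.arg(metrics, c("diffZ", "BLD", "DC", "JC"),
                         several.ok = TRUE)
    if (is.character(segmentations)) {
        if (is.null(geometry))
            stop("geometry is required when reading from CSV")
        segmentations <- readSegmentations(segmentations, geometry)
    }
    if (is.character(methodDisplacements)) {
        md <- readDisplacements(methodDisplacements, geometry)
        methodDisplacements <- md[[1L]]
    }
    if (is.character(scanInfo))
        scanInfo <- utils::read.csv(scanInfo, stringsAsFactors = FALSE)
    if (length(segmentations) < 3L)
        stop("the agreement stage needs at least 3 raters, got ",
             length(segmentations))

    ircTab <- do.call(rbind, lapply(segmentations, function(ss) {
        r <- intraRaterCoefficient(ss, toleranceUm)
        data.frame(rater = r$rater, irc = r$irc, counts = r$counts,
                   total = r$total)
    }))

    expertFields <- lapply(segmentations, function(ss) {
        f <- displacementFromTimepoints(ss)
        if (!is.null(scanInfo))
            f <- displacementFieldSet(dzValues(f), scanIds(f), rater(ss),
                                      geometry(ss), scanInfo = scanInfo)
        f
    })

    sims <- list()
    for (m in metrics) {
        sims[[m]] <- if (m == "diffZ") {
            fl <- expertFields
            if (!is.null(methodDisplacements))
                fl$method <- methodDisplacements
            pairwiseSimilarities(fl, "diffZ")
        } else {
            pairwiseSimilarities(segmentations, m)
        }
    }

    wiRows <- list()
    for (m in names(sims)) for (id in raterIds(sims[[m]]))
        wiRows[[length(wiRows) + 1L]] <- data.frame(
            rater = id, metric = m, wi = williamsIndex(sims[[m]], id)$wi)
    wiTab <- do.call(rbind, wiRows)

    methodLOO <- NULL
    if (!is.null(methodDisplacements) && "diffZ" %in% names(sims) &&
        nrow(similarityValues(sims$diffZ)) >= 4L)
        methodLOO <- williamsIndexLOO(sims$diffZ, "method")

    power <- NULL
    if (!is.null(methodDisplacements))
        power <- powerSummary(expertFields, methodDisplacements,
                              scanInfo = scanInfo, alpha = alpha,
                              mode = ttestMode)

    report <- structure(list(
        irc = ircTab, similarity = sims, wi = wiTab,
        methodLOO = methodLOO, power = power,
        params = list(toleranceUm = toleranceUm, alpha = alpha,
                      metrics = metrics, ttestMode = ttestMode)),
        class = "agreementReport")
    if (!is.null(outDir)) writeReport(report, outDir)
    report
}

#' Write an agreement report to disk
#'
#' Emits \code{irc.csv}, one \code{similarity_<metric>.csv} per metric
#' (tidy pairs), \code{williams_index.csv}, \code{agreement_report.csv}
#' (one row per rater: IRC plus WI per metric and the method's
#' leave-one-out range), \code{power_loo_ttests.csv}, interval/region
#' tables when available, and \code{summary.json}.
#'
#' @param report an \code{agreementReport} from \code{\link{runPipeline}}.
#' @param outDir output directory (created if missing).
#' @return \code{outDir}, invisibly.
#' @export
writeReport <- function(report, outDir) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(report$irc, file.path(outDir, "irc.csv"),
                     row.names = FALSE)
    for (m in names(report$similarity)) {
        v <- similarityValues(report$similarity[[m]])
        ids <- rownames(v)
        idx <- which(upper.tri(v), arr.ind = TRUE)
        tidy <- data.frame(metric = m, rater_a = ids[idx[, 1L]],
                           rater_b = ids[idx[, 2L]], value = v[idx])
        utils::write.csv(tidy,
                         file.path(outDir, sprintf("similarity_%s.csv", m)),
                         row.names = FALSE)
    }
    utils::write.csv(report$wi, file.path(outDir, "williams_index.csv"),
                     row.names = FALSE)

    wide <- stats::reshape(report$wi, idvar = "rater", timevar = "metric",
                           direction = "wide")
    colnames(wide) <- sub("^wi\\.", "WI_", colnames(wide))
    agg <- merge(report$irc[, c("rater", "irc")], wide, by = "rater",
                 all = TRUE)
    if (!is.null(report$methodLOO)) {
        agg$LOO_min <- ifelse(agg$rater == "method",
                              report$methodLOO$looMin, NA)
        agg$LOO_max <- ifelse(agg$rater == "method",
                              report$methodLOO$looMax, NA)
    }
    utils::write.csv(agg, file.path(outDir, "agreement_report.csv"),
                     row.names = FALSE)

    if (!is.null(report$power)) {
        utils::write.csv(report$power$looTests,
                         file.path(outDir, "power_loo_ttests.csv"),
                         row.names = FALSE)
        if (!is.null(report$power$intervalTable))
            utils::write.csv(report$power$intervalTable,
                             file.path(outDir, "displacement_by_interval.csv"),
                             row.names = FALSE)
        if (!is.null(report$power$regionTable))
            utils::write.csv(report$power$regionTable,
                             file.path(outDir, "displacement_by_region.csv"),
                             row.names = FALSE)
    }

    summary <- list(
        params = report$params,
        irc = stats::setNames(as.list(report$irc$irc), report$irc$rater),
        wi = report$wi,
        method_loo = if (!is.null(report$methodLOO))
            list(min = report$methodLOO$looMin,
                 max = report$methodLOO$looMax),
        power = if (!is.null(report$power)) report$power$looTests)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    invisible(outDir)
}

#' @export
print.agreementReport <- function(x, ...) {
    cat("Agreement report (l =", x$params$toleranceUm, "um, alpha =",
        x$params$alpha, ")\n\nIRC per rater:\n")
    print(x$irc, row.names = FALSE)
    cat("\nWilliams' index:\n")
    print(x$wi, row.names = FALSE)
    if (!is.null(x$methodLOO))
        cat(sprintf("\nMethod leave-one-out WI range: [%.4f, %.4f]\n",
                    x$methodLOO$looMin, x$methodLOO$looMax))
    if (!is.null(x$power)) { cat("\n"); print(x$power) }
    invisible(x)
}
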