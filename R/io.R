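#' Write a dataset to delimited text tables
#'
#' Writes one comma-delimited event table per sample (columns `fsc`,
#' `ssc`, `red`, `green`; file `{variant}_{replicate}_{time}min.csv`),
#' one two-column growth table per variant/replicate
#' (`{variant}_{replicate}_growth.csv` with `time_min`, `od600`), and a
#' YAML manifest listing the schedule, the variant Tm map, the
#' generator parameters and the seed. Numeric values are written with
#' full round-trip precision so [readDataset()] reproduces the dataset
#' exactly.
#'
#' @param dataset a [ReporterDataset-class].
#' @param outDir output directory (created if needed).
#'
#' @return Invisibly, the manifest list (also written as
#'   `manifest.yaml`).
#' @seealso [readDataset()]
#' @export
writeDataset <- function(dataset, outDir) {
    stopifnot(is(dataset, "ReporterDataset"))
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir, call. = FALSE)
    eventTables <- lapply(dataset@samples, function(s) {
        fn <- sprintf("%s_%d_%smin.csv", s@variant, s@replicate,
            format(s@timeMin))
        readr::write_csv(s@events[, c("fsc", "ssc", "red", "green")],
            file.path(outDir, fn), progress = FALSE)
        list(variant = s@variant, replicate = s@replicate,
            time_min = s@timeMin, file = fn)
    })
    gcs <- dataset@growthCurves
    growthTables <- list()
    if (nrow(gcs) > 0L) {
        keys <- unique(gcs[, c("variant", "replicate")])
        growthTables <- lapply(seq_len(nrow(keys)), function(i) {
            v <- keys$variant[i]; r <- keys$replicate[i]
            fn <- sprintf("%s_%d_growth.csv", v, r)
            sub <- gcs[gcs$variant == v & gcs$replicate == r,
                c("time_min", "od600")]
            readr::write_csv(sub, file.path(outDir, fn), progress = FALSE)
            list(variant = v, replicate = r, file = fn)
        })
    }
    manifest <- list(
        schedule = sort(unique(vapply(dataset@samples, sampleTime,
            numeric(1)))),
        variants = as.list(tmMap(dataset@panel)),
        wild_type = dataset@panel@name[dataset@panel@wildType],
        parameters = paramsAsList(dataset@params),
        seed = dataset@seed,
        event_tables = eventTables,
        growth_tables = growthTables)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"),
        precision = 17L)
    invisible(manifest)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir directory containing `manifest.yaml` and the tables.
#' @return A [ReporterDataset-class] equal field-by-field to the one
#'   written.
#' @export
readDataset <- function(dir) {
    mf <- file.path(dir, "manifest.yaml")
    if (!file.exists(mf))
        stop("no manifest.yaml under ", dir, call. = FALSE)
    manifest <- yaml::read_yaml(mf)
    tm <- unlist(manifest$variants)
    panel <- variantPanel(names(tm), as.numeric(tm),
        wildType = names(tm) %in% manifest$wild_type)
    params <- paramsFromList(manifest$parameters)
    samples <- lapply(manifest$event_tables, function(e) {
        ev <- as.data.frame(data.table::fread(file.path(dir, e$file)))
        timepointSample(e$variant, e$replicate, e$time_min, ev)
    })
    gcs <- lapply(manifest$growth_tables, function(g) {
        tab <- as.data.frame(data.table::fread(file.path(dir, g$file)))
        data.frame(variant = g$variant, replicate = g$replicate, tab)
    })
    gcdf <- if (length(gcs)) do.call(rbind, gcs) else
        data.frame(variant = character(), replicate = integer(),
            time_min = numeric(), od600 = numeric())
    new("ReporterDataset", samples = samples, growthCurves = gcdf,
        panel = panel, params = params,
        seed = as.integer(manifest$seed))
}
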