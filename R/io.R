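#' Read a Ct table in wide or long layout
#'
#' Reads a tabular file of cycle-threshold values into a
#' [CtExperiment-class]. Two layouts are accepted: *wide* (first column
#' sample name, second column group, one further column per gene) and
#' *long* (exactly four columns: sample, group, gene, Ct). Supported
#' file types are comma-separated (`csv`), tab-separated (`tsv`, the
#' assumption for `.txt`), and Excel (`xlsx`/`xls`, first sheet).
#' Non-numeric Ct cells (blank, `"Undetermined"`, `"NA"`, `">40"`, ...)
#' become missing values with a warning; imputation is deliberately not
#' performed. A load summary (samples, genes, group levels) is messaged.
#'
#' With `layout = "auto"` the wide and long interpretations are both
#' tried; if a four-column file is valid under both, the call fails
#' loudly rather than guessing.
#'
#' @param path path to the input file.
#' @param layout `"wide"`, `"long"`, or `"auto"`.
#' @param filetype `"csv"`, `"tsv"`, `"xlsx"`, or `"auto"` (from the
#'   file extension).
#' @return A [CtExperiment-class] (replicate rows, if any, not yet
#'   collapsed; see [collapseReplicates()]).
#' @seealso [readSampleMetadata()], [collapseReplicates()]
#' @export
readCtTable <- function(path, layout = c("auto", "wide", "long"),
                        filetype = c("auto", "csv", "tsv", "xlsx")) {
    layout <- match.arg(layout)
    filetype <- match.arg(filetype)
    if (!file.exists(path)) stop("file not found: ", path)
    if (filetype == "auto") {
        ext <- tolower(tools::file_ext(path))
        filetype <- switch(ext,
            csv = "csv", txt = "tsv", tsv = "tsv",
            xlsx = "xlsx", xls = "xlsx",
            stop("cannot infer file type from extension '", ext,
                 "'; pass filetype explicitly"))
    }
    raw <- tryCatch(.readRaw(path, filetype), error = function(e)
        stop("verify the format of the input file (", conditionMessage(e), ")",
             call. = FALSE))
    if (ncol(raw) < 3)
        stop("verify the format of the input file: ",
             "need sample and group columns followed by Ct data")
    if (layout == "auto") layout <- .detectLayout(raw)
    tab <- if (layout == "wide") .parseWide(raw) else .parseLong(raw)
    message(sprintf("Loaded %d rows (%d unique samples), %d genes, %d groups",
        ncol(tab$ct), length(unique(colnames(tab$ct))),
        nrow(tab$ct), length(unique(tab$group))))
    CtExperiment(tab$ct, group = tab$group)
}

.readRaw <- function(path, filetype) {
    if (filetype == "xlsx") {
        df <- as.data.frame(readxl::read_excel(path, sheet = 1,
            col_types = "text", .name_repair = "minimal"))
    } else {
        df <- utils::read.table(path,
            sep = if (filetype == "csv") "," else "\t",
            header = TRUE, colClasses = "character", check.names = FALSE,
            quote = "\"", comment.char = "", na.strings = NULL,
            stringsAsFactors = FALSE)
    }
    df
}

.ctNumeric <- function(x) {
    # blank / textual tokens ("Undetermined", "NA", ">40") -> NA
    x <- trimws(as.character(x))
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    nonnum <- !is.na(x) & is.na(out)
    if (any(nonnum))
        warning(sum(nonnum), " non-numeric Ct cell(s) (e.g. '",
            x[nonnum][1], "') treated as missing", call. = FALSE)
    out
}

.colIsNumericish <- function(x) {
    x <- trimws(as.character(x))
    x <- x[!is.na(x) & x != ""]
    if (!length(x)) return(TRUE)
    mean(!is.na(suppressWarnings(as.numeric(x)))) >= 0.5
}

.detectLayout <- function(raw) {
    wideOK <- ncol(raw) >= 3 &&
        all(vapply(raw[-(1:2)], .colIsNumericish, logical(1))) &&
        !anyDuplicated(colnames(raw)[-(1:2)])
    longOK <- ncol(raw) == 4 &&
        .colIsNumericish(raw[[4]]) && !.colIsNumericish(raw[[3]])
    if (wideOK && longOK)
        stop("ambiguous layout: file is readable as both wide and long; ",
             "pass layout explicitly")
    if (wideOK) return("wide")
    if (longOK) return("long")
    stop("verify the format of the input file: ",
         "neither wide nor long layout fits")
}

.parseWide <- function(raw) {
    genes <- colnames(raw)[-(1:2)]
    genes <- trimws(genes)
    if (anyDuplicated(genes))
        stop("duplicate gene columns: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    ct <- t(vapply(raw[-(1:2)], .ctNumeric, numeric(nrow(raw))))
    if (nrow(raw) == 1) ct <- matrix(ct, ncol = 1)
    rownames(ct) <- genes
    colnames(ct) <- trimws(raw[[1]])
    list(ct = ct, group = trimws(raw[[2]]))
}

.parseLong <- function(raw) {
    if (ncol(raw) != 4)
        stop("verify the format of the input file: ",
             "long layout needs exactly 4 columns (sample, group, gene, Ct)")
    sample <- trimws(raw[[1]]); group <- trimws(raw[[2]])
    gene <- trimws(raw[[3]]); ct <- .ctNumeric(raw[[4]])
    key <- paste(sample, group, sep = "\r")
    dup <- duplicated(paste(key, gene, sep = "\r"))
    if (any(dup)) {
        # repeated sample x gene rows are technical replicates: keep all
        # by suffixing a replicate index on the pivot, then let the
        # caller collapse; here we instead widen replicate sets into
        # separate sample rows sharing the identifier.
        rep_idx <- stats::ave(seq_along(key),
            paste(key, gene, sep = "\r"), FUN = seq_along)
        key <- paste(key, rep_idx, sep = "\r")
    }
    ukey <- unique(key)
    genes <- unique(gene)
    m <- matrix(NA_real_, nrow = length(genes), ncol = length(ukey),
        dimnames = list(genes, NULL))
    m[cbind(match(gene, genes), match(key, ukey))] <- ct
    parts <- strsplit(ukey, "\r", fixed = TRUE)
    colnames(m) <- vapply(parts, `[[`, character(1), 1)
    list(ct = m, group = vapply(parts, `[[`, character(1), 2))
}

#' Read a per-sample metadata table
#'
#' Reads secondary categorical sample information: the first column is
#' the sample identifier, each further column one categorical variable.
#' For Excel input this is the optional second sheet of the Ct workbook.
#'
#' @param path file path (csv/tsv/xlsx).
#' @param sheet sheet number for Excel input (default 2, the metadata
#'   sheet convention).
#' @param filetype as in [readCtTable()].
#' @return A data.frame whose first column is `sample`.
#' @export
readSampleMetadata <- function(path, sheet = 2,
                               filetype = c("auto", "csv", "tsv", "xlsx")) {
    filetype <- match.arg(filetype)
    if (filetype == "auto") {
        ext <- tolower(tools::file_ext(path))
        filetype <- switch(ext, csv = "csv", txt = "tsv", tsv = "tsv",
            xlsx = "xlsx", xls = "xlsx",
            stop("cannot infer file type for metadata"))
    }
    df <- if (filetype == "xlsx")
        as.data.frame(readxl::read_excel(path, sheet = sheet,
            col_types = "text", .name_repair = "minimal"))
    else .readRaw(path, filetype)
    if (ncol(df) < 2)
        stop("metadata needs a sample column plus at least one variable")
    names(df)[1] <- "sample"
    df$sample <- trimws(df$sample)
    df
}

#' Collapse technical replicates by geometric mean
#'
#' Rows sharing a sample identifier are technical replicates of the same
#' sample; their Ct values are collapsed per gene to the geometric mean
#' of the non-missing replicate measurements (all-missing stays
#' missing). Replicates must agree on the primary group; a conflicting
#' group label is an error naming the sample. The operation is
#' idempotent and invariant to replicate row order.
#'
#' @param x a [CtExperiment-class].
#' @return A collapsed [CtExperiment-class] with unique sample ids.
#' @examples
#' ct <- matrix(c(20, 45), 1, 2, dimnames = list("g", c("s1", "s1")))
#' ctValues(collapseReplicates(CtExperiment(ct, c("A", "A"))))  # 30
#' @export
collapseReplicates <- function(x) {
    stopifnot(is(x, "CtExperiment"))
    ids <- colnames(x)
    grp <- sampleGroups(x)
    conflict <- vapply(split(grp, ids), function(g)
        length(unique(g)) > 1, logical(1))
    if (any(conflict))
        stop("conflicting primary group for replicate sample(s): ",
             paste(names(conflict)[conflict], collapse = ", "))
    uid <- unique(ids)
    ct <- ctValues(x)
    geo <- function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) NA_real_ else exp(mean(log(v)))
    }
    out <- vapply(uid, function(id) {
        cols <- ct[, ids == id, drop = FALSE]
        apply(cols, 1, geo)
    }, numeric(nrow(ct)))
    if (nrow(ct) == 1) out <- matrix(out, nrow = 1)
    dimnames(out) <- list(rownames(ct), uid)
    cd <- colData(x)[match(uid, ids), , drop = FALSE]
    CtExperiment(out, group = as.character(cd$group),
        sampleData = as.data.frame(cd[, setdiff(colnames(cd), "group"),
                                      drop = FALSE]),
        collapsed = TRUE)
}

#' Rename genes
#'
#' Replace gene (row) names via a mapping of old name to new name, e.g.
#' to expand plate-coded housekeeping labels to gene symbols. Ct values
#' are untouched.
#'
#' @param x a [CtExperiment-class] or [NormalizedSet-class].
#' @param mapping named character vector: `c(old = "new", ...)`.
#' @return `x` with updated gene names.
#' @examples
#' ct <- matrix(20, 1, 1, dimnames = list("A", "s1"))
#' geneNames(renameGenes(CtExperiment(ct, "G1"), c(A = "ACTB")))
#' @export
renameGenes <- function(x, mapping) {
    if (!length(mapping)) return(x)
    if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
        stop("mapping must be a named character vector (old = new)")
    unknown <- setdiff(names(mapping), rownames(x))
    if (length(unknown))
        stop("unknown gene(s) in mapping: ", paste(unknown, collapse = ", "))
    nm <- rownames(x)
    nm[match(names(mapping), nm)] <- unname(mapping)
    if (anyDuplicated(nm))
        stop("rename would create duplicate gene name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    rownames(x) <- nm
    validObject(x)
    x
}

#' Join secondary sample metadata
#'
#' Adds the metadata variables as secondary per-sample columns, matched
#' by sample identifier. Samples absent from the metadata get missing
#' values (with a warning); metadata rows for unknown samples are
#' ignored (with a warning); duplicate metadata sample ids are an error.
#'
#' @param x a collapsed [CtExperiment-class].
#' @param meta a data.frame from [readSampleMetadata()] (first column
#'   sample id).
#' @return `x` with extended `colData`.
#' @export
joinMetadata <- function(x, meta) {
    stopifnot(is(x, "CtExperiment"), is.data.frame(meta), ncol(meta) >= 2)
    ids <- trimws(as.character(meta[[1]]))
    if (anyDuplicated(ids))
        stop("duplicate sample id(s) in metadata: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    extra <- setdiff(ids, colnames(x))
    if (length(extra))
        warning(length(extra), " metadata row(s) for unknown sample(s) ignored",
            call. = FALSE)
    idx <- match(colnames(x), ids)
    if (anyNA(idx))
        warning(sum(is.na(idx)),
            " sample(s) missing from metadata; secondary values set missing",
            call. = FALSE)
    for (v in names(meta)[-1])
        colData(x)[[v]] <- as.character(meta[[v]])[idx]
    validObject(x)
    x
}

#' Write / read a normalized table as CSV
#'
#' `writeNormalized()` writes a [NormalizedSet-class] as CSV with
#' columns `sample`, `group`, then one -deltaCt column per target gene;
#' missing values are empty cells. `readNormalized()` reads such a file
#' back (the housekeeping provenance is recorded in a `# normalizers:`
#' comment line and recovered on read).
#'
#' @param x a non-empty [NormalizedSet-class].
#' @param path output (or input) CSV path.
#' @return `writeNormalized()` returns `path` invisibly;
#'   `readNormalized()` a [NormalizedSet-class].
#' @export
writeNormalized <- function(x, path) {
    stopifnot(is(x, "NormalizedSet"), nrow(x) > 0, ncol(x) > 0)
    df <- data.frame(sample = colnames(x), group = sampleGroups(x),
        t(negDeltaCt(x)), check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(housekeeping(x)))
        writeLines(paste0("# normalizers: ",
            paste(housekeeping(x), collapse = " ")), con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeNormalized
#' @export
readNormalized <- function(path) {
    first <- readLines(path, n = 1)
    hk <- character(0)
    skip <- 0
    if (startsWith(first, "# normalizers:")) {
        hk <- strsplit(trimws(sub("# normalizers:", "", first)), " +")[[1]]
        skip <- 1
    }
    df <- utils::read.csv(path, check.names = FALSE, skip = skip,
        colClasses = "character")
    m <- t(vapply(df[-(1:2)], .ctAllowNegative, numeric(nrow(df))))
    if (nrow(df) == 1) m <- matrix(m, ncol = 1,
        dimnames = list(colnames(df)[-(1:2)], NULL))
    colnames(m) <- df[[1]]
    NormalizedSet(m, group = df[[2]], housekeeping = hk)
}

.ctAllowNegative <- function(x) {
    x <- trimws(as.character(x))
    x[x == ""] <- NA_character_
    suppressWarnings(as.numeric(x))
}
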