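## Tab-delimited I/O for the pipeline's table dialects, plus a GEO
## series-matrix reader (the optional path to the deposited accession).

#' Read an expression matrix and sample annotation
#'
#' The expression TSV has gene_id as the first column, sample identifiers
#' as header and log2 intensities in the body; the annotation TSV has
#' columns sample_id, subject_id, group, timepoint (optional meds, virus).
#' The two files must describe the same samples one-to-one.
#'
#' @param exprPath path to the expression TSV.
#' @param annotPath path to the annotation TSV.
#' @return an \linkS4class{AriCohort}.
#' @export
readExpressionTable <- function(exprPath, annotPath) {
    if (file.size(exprPath) == 0)
        stop("empty expression file: ", exprPath)
    expr <- utils::read.delim(exprPath, check.names = FALSE,
                              colClasses = "character")
    if (ncol(expr) < 2L || nrow(expr) == 0L)
        stop("malformed expression file: need gene_id plus >= 1 sample")
    geneIds <- expr[[1L]]
    if (anyDuplicated(geneIds))
        stop("duplicate gene ids: ",
             paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
    body <- as.matrix(expr[, -1L, drop = FALSE])
    Y <- suppressWarnings(apply(body, 2L, as.numeric))
    if (nrow(expr) == 1L) Y <- matrix(Y, nrow = 1L,
                                      dimnames = list(NULL, colnames(body)))
    bad <- which(is.na(Y) & body != "NA", arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf("non-numeric cell at row %d (gene %s), column '%s'",
                     bad[1L, 1L], geneIds[bad[1L, 1L]],
                     colnames(Y)[bad[1L, 2L]]))
    }
    rownames(Y) <- geneIds

    ann <- utils::read.delim(annotPath, stringsAsFactors = FALSE)
    cols <- colnames(ann)
    if ("subject_id" %in% cols && !"subject" %in% cols)
        ann$subject <- ann$subject_id
    need <- c("sample_id", "subject", "group", "timepoint")
    if (!all(need %in% colnames(ann)))
        stop("annotation lacks required columns: ",
             paste(setdiff(need, colnames(ann)), collapse = ", "))
    missing <- setdiff(colnames(Y), ann$sample_id)
    if (length(missing))
        stop("sample(s) in expression header missing from annotation: ",
             paste(missing, collapse = ", "))
    extra <- setdiff(ann$sample_id, colnames(Y))
    if (length(extra))
        stop("annotation sample(s) missing from expression matrix: ",
             paste(extra, collapse = ", "))
    ann <- ann[match(colnames(Y), ann$sample_id), , drop = FALSE]
    rownames(ann) <- ann$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = Y),
        colData = S4Vectors::DataFrame(ann),
        rowData = S4Vectors::DataFrame(gene_id = geneIds))
    new("AriCohort", se)
}

#' Write an expression matrix and sample annotation
#'
#' Inverse of \code{\link{readExpressionTable}} on canonical files.
#'
#' @param cohort an \linkS4class{AriCohort}.
#' @param exprPath,annotPath output paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionTable <- function(cohort, exprPath, annotPath) {
    Y <- SummarizedExperiment::assay(cohort, "log2")
    df <- data.frame(gene_id = rownames(Y), Y, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ann <- sampleAnnotation(cohort)
    ann$subject_id <- ann$subject
    keep <- intersect(c("sample_id", "subject_id", "group", "timepoint",
                        "meds", "virus"), colnames(ann))
    utils::write.table(ann[, keep], annotPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(exprPath, annotPath))
}

#' Write the planted truth of a synthetic cohort
#' @param cohort an \linkS4class{AriCohort} from \code{\link{simulateCohort}}.
#' @param path output TSV path.
#' @export
writePlantedTruth <- function(cohort, path) {
    truth <- plantedTruth(cohort)
    off <- plantedOffsets(cohort)
    df <- data.frame(gene_id = truth$gene_id, class = truth$class,
                     off, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write the long-format moderated statistics table
#' @param results a \linkS4class{ContrastResults}.
#' @param path output TSV path.
#' @export
writeContrastTable <- function(results, path) {
    utils::write.table(deTable(results), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a ranked signature profile
#' @param profile a \linkS4class{SignatureProfile}.
#' @param path output TSV path.
#' @export
writeProfile <- function(profile, path) {
    df <- data.frame(rank = seq_along(profile@genes),
                     gene_id = profile@genes,
                     loading = profile@loadings,
                     direction = profile@direction)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a membership table and its Venn-region summary
#' @param mem a \linkS4class{MembershipTable}.
#' @param path output TSV path; the region summary goes to
#'   \code{<path>.regions.tsv}.
#' @export
writeMembership <- function(mem, path) {
    utils::write.table(membership(mem), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(vennRegions(mem), paste0(path, ".regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write per-subject clinical series
#'
#' Emits the diary table (subject_id, day_index, phase, symptom_score,
#' puffs, pef), the per-visit table (subject_id, visit, fev1, eno) and the
#' subject table (subject_id, group, care_seeking, planted).
#'
#' @param seriesList named list of \linkS4class{ClinicalSeries}.
#' @param diaryPath,visitPath,subjectPath output TSV paths.
#' @export
writeClinicalTables <- function(seriesList, diaryPath, visitPath,
                                subjectPath) {
    diary <- do.call(rbind, lapply(seriesList, function(s) {
        rbind(data.frame(subject_id = s@subject, day_index = s@baseline$day,
                         phase = "baseline",
                         symptom_score = s@baseline$symptom,
                         puffs = s@baseline$puffs, pef = s@baseline$pef),
              data.frame(subject_id = s@subject, day_index = s@illness$day,
                         phase = "illness",
                         symptom_score = s@illness$symptom,
                         puffs = s@illness$puffs, pef = s@illness$pef))
    }))
    visits <- do.call(rbind, lapply(seriesList, function(s)
        data.frame(subject_id = s@subject, s@visits)))
    subjects <- do.call(rbind, lapply(seriesList, function(s)
        data.frame(subject_id = s@subject, group = s@group,
                   care_seeking = s@careSeeking, planted = s@planted)))
    for (w in list(list(diary, diaryPath), list(visits, visitPath),
                   list(subjects, subjectPath)))
        utils::write.table(w[[1L]], w[[2L]], sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(c(diaryPath, visitPath, subjectPath))
}

#' Read per-subject clinical series written by
#' \code{\link{writeClinicalTables}}
#'
#' @param diaryPath,visitPath,subjectPath input TSV paths.
#' @return named list of \linkS4class{ClinicalSeries}.
#' @export
readClinicalTables <- function(diaryPath, visitPath, subjectPath) {
    diary <- utils::read.delim(diaryPath, stringsAsFactors = FALSE)
    visits <- utils::read.delim(visitPath, stringsAsFactors = FALSE)
    subjects <- utils::read.delim(subjectPath, stringsAsFactors = FALSE)
    out <- vector("list", nrow(subjects))
    names(out) <- subjects$subject_id
    for (i in seq_len(nrow(subjects))) {
        sid <- subjects$subject_id[i]
        d <- diary[diary$subject_id == sid, , drop = FALSE]
        mk <- function(ph) {
            z <- d[d$phase == ph, , drop = FALSE]
            data.frame(day = z$day_index, symptom = z$symptom_score,
                       puffs = z$puffs, pef = z$pef)
        }
        v <- visits[visits$subject_id == sid,
                    c("visit", "fev1", "eno"), drop = FALSE]
        rownames(v) <- NULL
        out[[i]] <- new("ClinicalSeries", subject = sid,
                        group = subjects$group[i],
                        baseline = mk("baseline"), illness = mk("illness"),
                        visits = v,
                        careSeeking = isTRUE(subjects$care_seeking[i]),
                        planted = as.logical(subjects$planted[i]))
    }
    out
}

#' Parse a GEO series-matrix file into the pipeline's tables
#'
#' Reads the \code{!series_matrix_table} block as the expression matrix
#' and the \code{!Sample_*} header lines as annotation. Sample
#' characteristics lines of the form \code{key: value} become annotation
#' columns; when absent, the corresponding fields are left empty with a
#' warning. This supports the optional reproduction path from the public
#' accession; it is never required by the synthetic pipeline.
#'
#' @param path path to an uncompressed (or gz) series-matrix file.
#' @return list with elements \code{matrix} (genes x samples) and
#'   \code{annotation} (data.frame).
#' @export
readSeriesMatrix <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt")
           else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    if (!length(lines)) stop("empty series-matrix file")
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
        stop("series-matrix table block not found")
    tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                             check.names = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- as.character(tab[[1L]])
    storage.mode(m) <- "double"

    getField <- function(tag) {
        ln <- grep(paste0("^!", tag, "\t"), lines, value = TRUE)
        if (!length(ln)) return(NULL)
        v <- strsplit(ln[1L], "\t")[[1L]][-1L]
        gsub('^"|"$', "", v)
    }
    acc <- getField("Sample_geo_accession")
    title <- getField("Sample_title")
    ann <- data.frame(sample_id = if (!is.null(acc)) acc else colnames(m),
                      title = if (!is.null(title)) title else "",
                      stringsAsFactors = FALSE)
    charLines <- grep("^!Sample_characteristics_ch1\t", lines, value = TRUE)
    if (!length(charLines)) {
        warning("no sample-characteristics lines; annotation fields empty")
    } else {
        for (ln in charLines) {
            v <- gsub('^"|"$', "", strsplit(ln, "\t")[[1L]][-1L])
            kv <- strsplit(v, ":\\s*")
            keys <- unique(vapply(kv, `[`, character(1), 1L))
            key <- keys[nzchar(keys)][1L]
            ann[[make.names(key)]] <-
                vapply(kv, function(z)
                    if (length(z) > 1L) paste(z[-1L], collapse = ":")
                    else NA_character_, character(1))
        }
    }
    colnames(m) <- ann$sample_id
    list(matrix = m, annotation = ann)
}

#' Fetch a GEO series matrix by accession (optional; requires network)
#'
#' Validates the accession, downloads the series-matrix file and parses it
#' with \code{\link{readSeriesMatrix}}. Never used by the synthetic
#' pipeline or the test suite.
#'
#' @param accession a GEO series accession such as \code{"GSE46171"}.
#' @param destdir download directory (default tempdir()).
#' @return see \code{\link{readSeriesMatrix}}.
#' @export
fetchGeoSeries <- function(accession, destdir = tempdir()) {
    if (!grepl("^GSE[0-9]+$", accession))
        stop("malformed GEO series accession: ", accession)
    stub <- sub("[0-9]{1,3}$", "nnn", accession)
    url <- sprintf(paste0(
        "https://ftp.ncbi.nlm.nih.gov/geo/series/%s/%s/matrix/",
        "%s_series_matrix.txt.gz"), stub, accession, accession)
    dest <- file.path(destdir, paste0(accession, "_series_matrix.txt.gz"))
    status <- utils::download.file(url, dest, mode = "wb", quiet = TRUE)
    if (status != 0L) stop("download failed for ", accession)
    readSeriesMatrix(dest)
}
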