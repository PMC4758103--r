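#' Read gene sets from a GMT file
#'
#' Each line holds at least three tab-separated fields: set name, description,
#' then the member gene identifiers. Duplicated members within a set are
#' dropped with a warning; duplicated set names and empty member lists are
#' errors.
#'
#' @param path Path to a GMT file.
#' @return A \linkS4class{GeneSetList}.
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
        nm <- f[1]
        if (nm %in% names(sets))
            stop(sprintf("duplicated gene-set name at line %d: %s", i, nm))
        members <- f[-(1:2)]
        members <- members[nzchar(members)]
        if (!length(members))
            stop(sprintf("gene set '%s' (line %d) has no members", nm, i))
        if (anyDuplicated(members)) {
            warning(sprintf("gene set '%s': %d duplicated member(s) dropped",
                            nm, sum(duplicated(members))))
            members <- unique(members)
        }
        sets[[nm]] <- members
    }
    GeneSetList(sets)
}

#' Write gene sets to a GMT file
#'
#' @param gs A \linkS4class{GeneSetList}.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return Invisibly, \code{path}.
#' @export
writeGeneSets <- function(gs, path, descriptions = NULL) {
    sets <- geneSets(gs)
    if (is.null(descriptions)) descriptions <- names(sets)
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}
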