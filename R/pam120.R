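## Score assigned to residue pairs absent from the substitution matrix
## (X, U, O, padding). It sits far below any similarity threshold in use so
## unknown codes can never be counted as similar.
.SCORE_SENTINEL <- -100L

.pamCache <- new.env(parent = emptyenv())

#' The PAM120 substitution matrix
#'
#' Returns the standard PAM120 point-accepted-mutation matrix (as distributed
#' with Biostrings), used to define "high similarity" between aligned residues.
#'
#' @return Symmetric integer matrix with residue one-letter codes as dimnames.
#' @examples
#' pam120Matrix()["E", "Q"]   # 2
#' @export
pam120Matrix <- function() {
    if (is.null(.pamCache$PAM120)) {
        e <- new.env()
        utils::data("PAM120", package = "Biostrings", envir = e)
        .pamCache$PAM120 <- e$PAM120
    }
    .pamCache$PAM120
}

#' Score a residue pair under PAM120
#'
#' Symmetric lookup into the PAM120 matrix. Codes absent from the matrix
#' (such as `X`, `U`, `O`, or padding characters) fall through to a sentinel
#' far below any similarity threshold; they are never an error.
#'
#' @param a,b Single one-letter residue codes (vectorised; recycled).
#' @return Integer score(s).
#' @examples
#' pam120Score("E", "Q")  # 2
#' pam120Score("Y", "F")  # 4
#' pam120Score("I", "L")  # 1
#' pam120Score("I", "F")  # 0
#' @export
pam120Score <- function(a, b) {
    .lookupScore(pam120Matrix(), a, b)
}

.lookupScore <- function(m, a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(as.character(a), n)
    b <- rep_len(as.character(b), n)
    ## padding marks are never residues, whatever the matrix contains
    ia <- match(a, rownames(m))
    ib <- match(b, colnames(m))
    ia[a %in% .PAD_CHARS] <- NA_integer_
    ib[b %in% .PAD_CHARS] <- NA_integer_
    out <- rep(.SCORE_SENTINEL, n)
    ok <- !is.na(ia) & !is.na(ib)
    out[ok] <- m[cbind(ia[ok], ib[ok])]
    out[is.na(out)] <- .SCORE_SENTINEL
    as.integer(out)
}

#' Construct a similarity rule
#'
#' @param matrix Symmetric integer substitution matrix; defaults to
#'   [pam120Matrix()].
#' @param threshold Integer; two aligned non-identical residues are "highly
#'   similar" iff their score is strictly greater than this. Default 1.
#' @return A [SimilarityRule-class] object.
#' @examples
#' rule <- similarityRule()
#' @export
similarityRule <- function(matrix = pam120Matrix(), threshold = 1L) {
    new("SimilarityRule", matrix = matrix, threshold = as.integer(threshold))
}

## Internal: score a pair under an arbitrary rule matrix, sentinel fallback.
.ruleScore <- function(rule, a, b) {
    .lookupScore(rule@matrix, a, b)
}
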