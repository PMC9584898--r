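## Canonical human alpha-synuclein (140 aa). The mouse sequence is derived
## from it by the seven known substitutions, the biologically salient one for
## this screen being S87N (asparagine cannot be phosphorylated).
.ASYN_HUMAN <- paste0(
    "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTK",
    "EQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP",
    "DNEAYEMPSEEGYQDYEPEA")

.ASYN_MOUSE_SUBS <- c(`53` = "T", `87` = "N", `100` = "M", `103` = "G",
                      `107` = "Y", `121` = "G", `122` = "S")

.asynMouse <- function() {
    s <- strsplit(.ASYN_HUMAN, "")[[1]]
    s[as.integer(names(.ASYN_MOUSE_SUBS))] <- .ASYN_MOUSE_SUBS
    paste(s, collapse = "")
}

#' Canonical alpha-synuclein sequences
#'
#' The canonical 140-residue human alpha-synuclein sequence, or the mouse
#' ortholog (which differs at seven positions, including an asparagine at
#' position 87 where the human protein carries a phosphorylatable serine).
#'
#' @param organism `"human"` or `"mouse"`.
#' @return A single character string of 140 residues.
#' @examples
#' substring(aSynSequence("human"), 129, 129)  # "S"
#' substring(aSynSequence("mouse"), 87, 87)    # "N"
#' @export
aSynSequence <- function(organism = c("human", "mouse")) {
    organism <- match.arg(organism)
    if (organism == "human") .ASYN_HUMAN else .asynMouse()
}

## Positions of the six default seed phosphosites on human aSyn.
.ASYN_SEED_POSITIONS <- c(39L, 87L, 125L, 129L, 133L, 136L)
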