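# shared fixtures, built in code

toyOrder <- function(n) {
  parseGeneOrder(paste(c(paste0("g", seq_len(n)), "CR"), collapse = " "))
}

# the observed S. latus arrangement of the duplicated block, as canonical
# positions: the 11-gene cluster then the 17-gene cluster (trnP excluded)
slatusBlockRanks <- function(withTrnP = FALSE) {
  r <- c(14, 15, 17, 20, 26, 30, 32, 33, 34, 35, 36,
         9, 10, 11, 12, 13, 16, 18, 19, 21, 22, 23, 24, 25, 27, 28, 29, 31)
  if (withTrnP) c(r, 37) else r
}

# canonical positions of the copy-1 survivor cluster
slatusCopy1Idx <- c(14, 15, 17, 20, 26, 30, 32, 33, 34, 35, 36)

# the intermediate order after loss (stage E): reconstruction target used
# across simulator and inference tests
stageEOrder <- function() {
  parseGeneOrder(paste(
    "trnF rrnS trnV rrnL trnL1 ND1 trnI trnQ CR trnC trnY trnS1 trnK trnR",
    "trnS2 ND5 ND6 trnE CYTB trnT CRII-remnant trnM ND2 trnW trnA trnN COI",
    "trnD COII ATP8 ATP6 COIII trnG ND3 ND4L ND4 trnH trnL2 trnP",
    "CRIII-remnant"))
}

# identity key of the event that generated a synthetic case, in the format
# of explanationKeys()
generatingKey <- function(case) {
  surv1 <- names(case@event@lossAssignment)[case@event@lossAssignment == "copy1"]
  paste(paste(case@event@insertionEdge, collapse = ">"),
        paste(sort(surv1), collapse = ","), sep = "|")
}

# independent split oracle: all positions s such that both sides of the cut
# are strictly increasing, by direct check
bruteSplits <- function(seq) {
  Filter(function(s) {
    a <- seq[seq_len(s)]
    b <- if (s < length(seq)) seq[(s + 1):length(seq)] else numeric(0)
    (!length(a) || all(diff(a) > 0)) && (!length(b) || all(diff(b) > 0))
  }, 0:length(seq))
}
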