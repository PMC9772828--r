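# shared fixture builders; everything is generated in code

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# toy genome: one plus-strand and one minus-strand two-exon transcript
toy_genome <- function() {
  c(chrP = "AAAAGTCCAGTTTT",
    chrM = "AAAACTGGACTTTT")
}

toy_transcripts <- function() {
  list(
    txP = transcript_model("txP", "gP", "chrP", "+",
                           data.frame(start = c(0, 10), end = c(4, 14))),
    txM = transcript_model("txM", "gM", "chrM", "-",
                           data.frame(start = c(0, 10), end = c(4, 14))))
}

# uniform-background PWM model where every column equals the background
flat_bp_model <- function() {
  m <- bp_model_pwm("CCCTAACAA")
  m$pwm[] <- 0.25
  m
}

# PWM with one dominant base per position (A everywhere), prob p
biased_bp_model <- function(p = 0.7) {
  m <- bp_model_pwm("AAAAAAAAA")
  m$pwm[] <- (1 - p) / 3
  m$pwm["A", ] <- p
  m
}

# donor maxent model identical to its background: every window scores 0
flat_donor_model <- function(window = 9L, site_kind = "donor") {
  base_probs <- stats::setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  comps <- lapply(seq_len(window), function(j)
    list(positions = j, probs = base_probs))
  maxent_model(site_kind, window = window, components = comps,
               check_consensus = FALSE)
}

random_intron <- function(len, seed) {
  set.seed(seed)
  paste0(paste(sample(c("A", "C", "G", "T"), len - 2, replace = TRUE),
               collapse = ""), "AG")
}
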