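
#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Upper-cases the input and maps T to U. Any remaining letter outside
#' A/C/G/U is an error.
#'
#' @param seq Character vector of sequences.
#' @return Character vector over the A/C/G/U alphabet.
#' @export
normalize_seq <- function(seq) {
  out <- chartr("t", "u", toupper(as.character(seq)))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("non-ACGU letter(s) after T->U normalization in sequence(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out
}

#' Reverse complement of RNA sequences
#'
#' Antiparallel Watson-Crick complement (A<->U, C<->G), the hybridization
#' geometry of a trigger bound to the 5' sensing region of a switch.
#'
#' @param seq Character vector of RNA (or DNA; T is normalized to U).
#' @return Character vector of reverse complements, RNA alphabet.
#' @examples
#' reverse_complement("AAA")   # "UUU"
#' reverse_complement("ACGU")  # "ACGU"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  comp <- chartr("ACGU", "UGCA", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Toehold switch architecture template
#'
#' Positional grammar of the canonical 59-nt switch: the 5' 30 nt are the
#' reverse complement of the trigger, an 11-nt conserved loop carries the
#' ribosome binding site, a 3-nt unpaired bulge (22-24) sits opposite the AUG
#' start codon (48-50), and two stem segments are tied to trigger positions by
#' reverse-complementarity so the hairpin base-pairs. All coordinates are
#' 1-based inclusive.
#'
#' The default conserved loop is a reconstruction of the canonical series
#' (it contains the Shine-Dalgarno octamer AGAGGAGA); every field is
#' user-configurable, so an alternative pairing map or loop is a data change,
#' not a code change.
#'
#' @param total_length Switch length (default 59).
#' @param trigger_region Integer pair, 1-based inclusive range bound by the
#'   trigger (default `c(1, 30)`).
#' @param conserved_segments Named list mapping `"start-end"` ranges to fixed
#'   letters.
#' @param dependency_rules List of rules, each `list(target = c(s, e),
#'   source = c(s, e))`, meaning the target range is the reverse complement of
#'   the source range.
#' @param bulge Integer pair: the unpaired bulge range.
#' @param mutable_positions Integer pair: the stem range varied by the
#'   enumeration optimizer.
#' @return An object of class `toehold_template`.
#' @examples
#' tmpl <- toehold_template()
#' tmpl$total_length
#' @export
toehold_template <- function(total_length = 59L,
                             trigger_region = c(1L, 30L),
                             conserved_segments = list(
                               "31-41" = "AACAGAGGAGA",
                               "48-50" = "AUG"
                             ),
                             dependency_rules = list(
                               list(target = c(42L, 47L), source = c(25L, 30L)),
                               list(target = c(51L, 59L), source = c(13L, 21L))
                             ),
                             bulge = c(22L, 24L),
                             mutable_positions = c(22L, 30L)) {
  tmpl <- structure(list(
    total_length = as.integer(total_length),
    trigger_region = as.integer(trigger_region),
    conserved_segments = lapply(conserved_segments, normalize_seq),
    dependency_rules = dependency_rules,
    bulge = as.integer(bulge),
    mutable_positions = as.integer(mutable_positions)
  ), class = "toehold_template")
  validate_template(tmpl)
  tmpl
}

parse_range <- function(key) as.integer(strsplit(key, "-", fixed = TRUE)[[1]])

range_seq <- function(r) seq.int(r[1], r[2])

validate_template <- function(tmpl) {
  covered <- range_seq(tmpl$trigger_region)
  for (key in names(tmpl$conserved_segments)) {
    r <- parse_range(key)
    if (nchar(tmpl$conserved_segments[[key]]) != r[2] - r[1] + 1L)
      stop("conserved segment ", key, " letters do not fit its range")
    covered <- c(covered, range_seq(r))
  }
  dep_targets <- integer(0)
  for (rule in tmpl$dependency_rules) {
    if (diff(rule$target) != diff(rule$source))
      stop("dependency target and source ranges differ in length")
    if (!all(range_seq(rule$source) %in% range_seq(tmpl$trigger_region)))
      stop("dependency source must lie inside the trigger region")
    dep_targets <- c(dep_targets, range_seq(rule$target))
    covered <- c(covered, range_seq(rule$target))
  }
  if (anyDuplicated(covered))
    stop("template ranges overlap")
  if (!setequal(covered, seq_len(tmpl$total_length)))
    stop("template ranges must jointly cover 1..total_length")
  if (length(intersect(range_seq(tmpl$bulge), dep_targets)) > 0L)
    stop("bulge must not intersect dependency targets")
  invisible(tmpl)
}

#' @export
print.toehold_template <- function(x, ...) {
  cat("Toehold architecture template (", x$total_length, " nt)\n", sep = "")
  cat("  trigger region : ", x$trigger_region[1], "-", x$trigger_region[2],
      " (reverse complement of trigger)\n", sep = "")
  for (key in names(x$conserved_segments))
    cat("  conserved ", key, "  : ", x$conserved_segments[[key]], "\n", sep = "")
  for (rule in x$dependency_rules)
    cat("  pairing        : ", rule$target[1], "-", rule$target[2], " <- rc(",
        rule$source[1], "-", rule$source[2], ")\n", sep = "")
  cat("  bulge          : ", x$bulge[1], "-", x$bulge[2], " (unpaired)\n", sep = "")
  cat("  mutable stem   : ", x$mutable_positions[1], "-",
      x$mutable_positions[2], "\n", sep = "")
  invisible(x)
}

trigger_length <- function(tmpl) tmpl$trigger_region[2] - tmpl$trigger_region[1] + 1L

substr_vec <- function(x, r) substr(x, r[1], r[2])

`substr_vec<-` <- function(x, r, value) {
  substr(x, r[1], r[2]) <- value
  x
}

#' Assemble a toehold switch from a trigger
#'
#' Fills the full-length switch from a 30-nt trigger using the structural
#' rules of the template: the trigger region is the reverse complement of the
#' trigger, conserved segments are copied verbatim, and each dependent stem
#' segment is the reverse complement of its source slice.
#'
#' @param trigger Character vector of trigger sequences (length must match the
#'   template's trigger region).
#' @param template A [toehold_template()].
#' @return Character vector of assembled switches (vectorized over triggers).
#' @examples
#' assemble_switch(strrep("A", 30))
#' @export
assemble_switch <- function(trigger, template = toehold_template()) {
  trigger <- normalize_seq(trigger)
  tl <- trigger_length(template)
  if (any(nchar(trigger) != tl))
    stop("trigger length must be ", tl, " nt", call. = FALSE)
  switch_seq <- strrep("N", template$total_length)
  switch_seq <- rep(switch_seq, length(trigger))
  substr_vec(switch_seq, template$trigger_region) <- reverse_complement(trigger)
  for (key in names(template$conserved_segments)) {
    r <- parse_range(key)
    substr_vec(switch_seq, r) <- template$conserved_segments[[key]]
  }
  for (rule in template$dependency_rules) {
    src <- substr_vec(switch_seq, rule$source)
    substr_vec(switch_seq, rule$target) <- reverse_complement(src)
  }
  switch_seq
}

#' Validate a switch against a template
#'
#' Checks every conserved segment and every pairing dependency. A length
#' mismatch is an error (not a failed report), matching the contract that a
#' report describes a candidate of the right shape.
#'
#' @param switch Character scalar, candidate switch sequence.
#' @param template A [toehold_template()].
#' @return A list with `pass` (logical) and `violations` (character vector
#'   naming each violated constraint and its range).
#' @export
validate_switch <- function(switch, template = toehold_template()) {
  switch <- normalize_seq(switch)
  if (length(switch) != 1L) stop("validate_switch takes a single sequence")
  if (nchar(switch) != template$total_length)
    stop("switch length ", nchar(switch), " != template total_length ",
         template$total_length, call. = FALSE)
  violations <- character(0)
  for (key in names(template$conserved_segments)) {
    r <- parse_range(key)
    if (substr_vec(switch, r) != template$conserved_segments[[key]])
      violations <- c(violations, paste0("conserved ", key))
  }
  for (rule in template$dependency_rules) {
    expected <- reverse_complement(substr_vec(switch, rule$source))
    if (substr_vec(switch, rule$target) != expected)
      violations <- c(violations,
                      paste0("pairing ", rule$target[1], "-", rule$target[2],
                             "<-", rule$source[1], "-", rule$source[2]))
  }
  list(pass = length(violations) == 0L, violations = violations)
}

#' Repair a candidate sequence into a valid switch
#'
#' Projects an arbitrary full-length candidate onto the valid set: conserved
#' segments are overwritten with the template letters and each pairing
#' dependency is re-derived. With `authority = "trigger_side"` (default) the
#' source slice inside the trigger region is kept and the target stem segment
#' is recomputed from it; `"coding_side"` keeps the target and rewrites the
#' source. The bulge and all other free positions are never touched.
#' Idempotent by construction.
#'
#' @param candidate Character vector of full-length candidate sequences.
#' @param template A [toehold_template()].
#' @param authority `"trigger_side"` or `"coding_side"`.
#' @return Character vector of repaired, valid switches.
#' @export
fix_sequence <- function(candidate, template = toehold_template(),
                         authority = c("trigger_side", "coding_side")) {
  authority <- match.arg(authority)
  candidate <- normalize_seq(candidate)
  if (any(nchar(candidate) != template$total_length))
    stop("candidate length must be ", template$total_length, " nt", call. = FALSE)
  for (key in names(template$conserved_segments)) {
    r <- parse_range(key)
    substr_vec(candidate, r) <- template$conserved_segments[[key]]
  }
  for (rule in template$dependency_rules) {
    if (authority == "trigger_side") {
      src <- substr_vec(candidate, rule$source)
      substr_vec(candidate, rule$target) <- reverse_complement(src)
    } else {
      tgt <- substr_vec(candidate, rule$target)
      substr_vec(candidate, rule$source) <- reverse_complement(tgt)
    }
  }
  candidate
}

#' Extract the trigger encoded by a switch
#'
#' Inverse of [assemble_switch()] for the trigger region.
#'
#' @param switch Character vector of switches.
#' @param template A [toehold_template()].
#' @return Character vector of 30-nt triggers.
#' @export
switch_trigger <- function(switch, template = toehold_template()) {
  reverse_complement(substr_vec(normalize_seq(switch), template$trigger_region))
}

#' Tile a genome into candidate trigger windows
#'
#' Slides a fixed-width window along the forward strand with a fixed stride,
#' the screening design used to nominate candidate triggers from genomes or
#' transcript sets.
#'
#' @param genome Character scalar, the sequence to tile.
#' @param window Window width in nt (default 30).
#' @param stride Step between window starts in nt (default 5).
#' @return A data.frame with columns `start` (1-based) and `trigger`. A genome
#'   shorter than the window yields zero rows, with a warning.
#' @examples
#' tile_sequence(strrep("ACGU", 10))
#' @export
tile_sequence <- function(genome, window = 30L, stride = 5L) {
  genome <- normalize_seq(genome)
  if (length(genome) != 1L) stop("tile_sequence takes a single sequence")
  L <- nchar(genome)
  if (L < window) {
    warning("genome shorter than the window; no tiles produced")
    return(data.frame(start = integer(0), trigger = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- seq.int(1L, L - window + 1L, by = stride)
  data.frame(start = starts,
             trigger = substring(genome, starts, starts + window - 1L),
             stringsAsFactors = FALSE)
}

#' Size of the trigger sequence space
#'
#' Number of distinct triggers expressible under a template: 4^w for a
#' trigger region of width w. Computed in double precision; exact for the
#' default w = 30 because 4^30 = 2^60 is a representable power of two.
#'
#' @param template A [toehold_template()].
#' @return Numeric scalar, 4^(trigger width).
#' @export
trigger_space_size <- function(template = toehold_template()) {
  4^trigger_length(template)
}
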