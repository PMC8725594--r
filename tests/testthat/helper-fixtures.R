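# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The four ~1 Mb strain fixtures (slow to build; shared by discovery,
# generator and acceptance tests).
test_strain_fixtures <- function() {
  cached("strain_fixtures", function() build_strain_fixtures(seed = 1))
}

# A small annotated genome for fast profiling / promoter tests.
test_small_genome <- function() {
  cached("small_genome", function() {
    chr <- random_genome(2e5, gc = 0.619, seed = 42, name = "chr")
    ann <- random_annotation(chr, seed = 43)
    genome("toy", list(chr), annotation = ann)
  })
}

MOTIF_MODS <- c(
  GANTC = "m6A", RCGCCTC = "m4C", CGCANNNNNGTG = "m6A",
  TCGANNNNNNNNTCGA = "m6A", CAGANNNNNNNGTTG = "m6A", WNCCGATG = "m6A"
)

# Independent brute-force IUPAC scanner used as oracle for scan_motif:
# checks every start position and both strands with its own IUPAC table.
oracle_scan <- function(seq, iupac) {
  classes <- c(
    A = "A", C = "C", G = "G", T = "T",
    M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
    V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT"
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(toupper(seq), "")[[1]]
  k <- nchar(iupac)
  cols <- strsplit(toupper(iupac), "")[[1]]
  matches_at <- function(s, start) {
    all(vapply(seq_len(k), function(j) {
      grepl(s[start + j - 1L], classes[[cols[j]]], fixed = TRUE)
    }, logical(1)))
  }
  fwd <- integer(0)
  rev <- integer(0)
  rc_chars <- rev(unname(comp[chars]))
  for (s in seq_len(length(chars) - k + 1L)) {
    if (matches_at(chars, s)) fwd <- c(fwd, s)
    if (matches_at(rc_chars, s)) rev <- c(rev, s)
  }
  list(fwd = fwd, rev = rev)
}
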