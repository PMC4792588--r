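# Shared fixtures, built in code at test time.

ar_catalog <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- load_catalog(system.file("extdata", "ar_example.tsv",
                                          package = "arvscan"))
    cached
  }
})

# Long-form count table over all catalog junctions from a named list of
# named count vectors, e.g. make_counts(list(s1 = c("3-CE3" = 5))).
make_counts <- function(per_sample, catalog = ar_catalog()) {
  jn <- catalog$junctions
  do.call(rbind, lapply(names(per_sample), function(s) {
    cnt <- integer(nrow(jn))
    names(cnt) <- jn$label
    given <- per_sample[[s]]
    cnt[names(given)] <- given
    data.frame(sample_id = s, junction_label = jn$label, class = jn$class,
               count = as.integer(cnt), stringsAsFactors = FALSE)
  }))
}

# One alignment row in read_alignments() layout.
make_read <- function(pos0, cigar, mapq = 50L, sample_id = "s1",
                      chrom = "chrX", read_name = "r1",
                      is_secondary = FALSE, is_supplementary = FALSE) {
  data.frame(read_name = read_name, sample_id = sample_id, chrom = chrom,
             pos = as.integer(pos0), mapq = as.integer(mapq), cigar = cigar,
             is_secondary = is_secondary,
             is_supplementary = is_supplementary, stringsAsFactors = FALSE)
}

# A read spanning one catalog junction with the given anchor lengths.
spanning_read <- function(junction_label, left = 20L, right = 20L,
                          catalog = ar_catalog(), ...) {
  j <- catalog$junctions[catalog$junctions$label == junction_label, ]
  gap <- j$gap_end - j$gap_start
  make_read(j$gap_start - left,
            sprintf("%dM%dN%dM", left, gap, right), ...)
}

ar_transcripts <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- build_transcripts(ar_catalog(), ar_default_chains())
    cached
  }
})
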