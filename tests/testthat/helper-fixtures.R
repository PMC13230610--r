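# shared fixtures, built once per test run
fx <- midas_fixtures()

local_cache <- new.env()
cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

d108_unit <- function() cached("d108", fixture_unit("d108", seed = 1))
l560_unit <- function() cached("l560", fixture_unit("l560", seed = 1))

# strip gene prefix / -F suffix from a fixture array name -> variant label
fixture_label <- function(nm) sub("-F$", "", sub("^[^-]*-", "", sub("^ACh NeuBI-", "NeuBI-", nm)))

# wild-type protein of a unit's first CDS (stop trimmed)
unit_protein <- function(unit) {
  cds <- unit$cds[[1]]
  aa <- translate_dna(dna(substr(unclass(unit$sequence), cds[1] + 1L, cds[2])))
  sub("\\*.*$", "", aa)
}
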