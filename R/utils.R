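## Locale-independent ordering. All deterministic outputs (canonical
## conjunct order, sorted ids, serialized rows, tie-breaks for
## equivalence-class representatives) use byte-order comparison so that
## results do not depend on the session's collation locale.

.orderC <- function(...) {
  first <- ..1
  if (!length(first)) return(integer(0))
  order(..., method = "radix")
}

.sortC <- function(x) if (length(x)) x[.orderC(x)] else as.character(x)
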