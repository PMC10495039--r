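# small fixtures shared across test files; everything is built in code

toy_bank3 <- function() {
  item_bank(paste0("i", 1:3), rep("new", 3), c(1.2, 0.9, 1.6),
            list(c(-1, 0.5), c(-0.3, 1), c(0, 0.8)), rep(FALSE, 3))
}

study_bank <- function(seed = 1) {
  make_item_bank(4, 9, 5, c(1.2, 3.0), c(-2.5, 2.5), seed = seed)
}

anchor_part <- function(bank) bank$item_id[bank$instrument == "anchor"]
new_part <- function(bank) bank$item_id[bank$instrument == "new"]

default_partition <- function(bank) {
  list(anchor_part(bank), new_part(bank)[1:3], new_part(bank)[4:6],
       new_part(bank)[7:9])
}
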