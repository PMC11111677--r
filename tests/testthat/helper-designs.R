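# shared builders and independent oracles

# comparison groups with synthetic labels, e.g. sizes c(2, 3) ->
# diet{diet_1, diet_2}, genotype{genotype_1..3}
make_design <- function(sizes) {
  cats <- c("diet", "genotype", "treatment", "age", "temperature",
            "other")[seq_along(sizes)]
  lapply(seq_along(sizes), function(i) {
    comparison_group(cats[i], lapply(
      paste0(cats[i], "_", seq_len(sizes[i])), group_instance))
  })
}

# brute-force nested-loop enumeration of the label product, last group
# varying fastest; independent of generate_final_groups
enumerate_product <- function(label_lists) {
  out <- list(character(0))
  for (labels in label_lists) {
    nxt <- list()
    for (prefix in out) {
      for (l in labels) nxt[[length(nxt) + 1L]] <- c(prefix, l)
    }
    out <- nxt
  }
  out
}

final_groups_with_reps <- function(groups, reps) {
  fgs <- generate_final_groups(groups)
  lapply(seq_along(fgs), function(i)
    final_group(fgs[[i]]$assignment, reps[[((i - 1L) %% length(reps)) + 1L]]))
}

# random small design under the current RNG
random_sizes <- function(max_groups = 4L, max_instances = 5L) {
  n <- sample.int(max_groups, 1)
  sample.int(max_instances, n, replace = TRUE)
}

expect_rule_count <- function(report, rule, n) {
  rules <- vapply(report$issues, function(i) i$rule, character(1))
  expect_identical(sum(rules == rule), as.integer(n))
}
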