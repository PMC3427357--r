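# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately use naive algorithms unrelated to the
# package implementations they check.

# --- ORF: exhaustive scan over all (start, frame) pairs -------------------
brute_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  if (n >= 6) {
    for (start in 1:(n - 5)) {
      if (substr(s, start, start + 2) != "ATG") next
      j <- start + 3
      while (j + 2 <= n) {
        cod <- substr(s, j, j + 2)
        if (cod %in% stops) {
          len <- j + 2 - start + 1
          if (is.null(best) || len > best$length_nt) {
            best <- list(start = start - 1L, length_nt = len)
          }
          break
        }
        j <- j + 3
      }
    }
  }
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Transcript of `total_nt` whose longest ORF has exactly `orf_nt` nt
# (stop-inclusive): AT-only flanks (no G, hence no start codon) around
# ATG + (Ala)^k + TGA.
planted_orf_seq <- function(orf_nt, total_nt) {
  stopifnot(orf_nt %% 3 == 0, orf_nt >= 6, total_nt >= orf_nt)
  body <- paste0("ATG", strrep("GCT", orf_nt / 3 - 2), "TGA")
  pad <- total_nt - orf_nt
  left <- substr(strrep("TA", ceiling(pad / 2)), 1, floor(pad / 2))
  right <- substr(strrep("AT", ceiling(pad / 2)), 1, pad - floor(pad / 2))
  paste0(left, body, right)
}

# --- percentiles: O(n^2) count-at-or-below ---------------------------------
oracle_percentiles <- function(rpkm) {
  expressed <- rpkm[rpkm > 0]
  vapply(rpkm, function(x) {
    if (x <= 0) 0 else 100 * sum(expressed <= x) / length(expressed)
  }, numeric(1))
}

# --- coverage: naive per-base fill -----------------------------------------
oracle_fill <- function(df, span) {
  depth <- numeric(span)
  for (i in seq_len(nrow(df))) {
    for (p in (df$start[i] + 1):df$end[i]) depth[p] <- df$depth[i]
  }
  depth
}

# --- fragment calling: per-base run scanner --------------------------------
oracle_fragments <- function(depth, min_depth, min_len, max_zero_run) {
  ok <- depth >= min_depth
  frs <- list()
  i <- 1
  n <- length(ok)
  while (i <= n) {
    if (!ok[i]) { i <- i + 1; next }
    j <- i
    last_good <- i
    while (j <= n) {
      if (ok[j]) {
        last_good <- j
        j <- j + 1
      } else {
        k <- j
        while (k <= n && !ok[k]) k <- k + 1
        if (k <= n && (k - j) <= max_zero_run) j <- k else break
      }
    }
    if (last_good - i + 1 >= min_len) {
      frs[[length(frs) + 1]] <- c(i - 1, last_good)  # 0-based half-open
    }
    i <- j
  }
  if (length(frs) == 0) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  m <- do.call(rbind, frs)
  data.frame(start = m[, 1], end = m[, 2])
}

# --- merge: all-orders fixpoint on single-exon chains ----------------------
# Rows: data.frame(start, end, len, rpkm, pct, prov = I(list(...))).
# Joins any allowed adjacent pair in every possible order; returns the set of
# distinct terminal partitions (each a sorted signature string).
oracle_merge_all_orders <- function(rows, d, max_gap, lookup) {
  finals <- new.env()
  signature <- function(rs) {
    paste(sort(vapply(rs$prov, function(p) paste(sort(p), collapse = "+"),
                      "")), collapse = " | ")
  }
  join <- function(rs, i) {
    new <- rs[i, ]
    new$start <- min(rs$start[i], rs$start[i + 1])
    new$end <- max(rs$end[i], rs$end[i + 1])
    new$rpkm <- (rs$rpkm[i] * rs$len[i] + rs$rpkm[i + 1] * rs$len[i + 1]) /
      (rs$len[i] + rs$len[i + 1])
    new$len <- rs$len[i] + rs$len[i + 1]
    new$pct <- lookup(new$rpkm)
    new$prov <- I(list(c(rs$prov[[i]], rs$prov[[i + 1]])))
    rbind(if (i > 1) rs[seq_len(i - 1), ], new,
          if (i + 1 < nrow(rs)) rs[seq.int(i + 2, nrow(rs)), ])
  }
  recurse <- function(rs) {
    allowed <- which(
      rs$start[-1] - rs$end[-nrow(rs)] <= max_gap &
        abs(rs$pct[-1] - rs$pct[-nrow(rs)]) <= d)
    if (nrow(rs) < 2 || length(allowed) == 0) {
      assign(signature(rs), TRUE, envir = finals)
      return(invisible())
    }
    for (i in allowed) recurse(join(rs, i))
  }
  recurse(rows)
  ls(finals)
}

# --- geometry: coordinate mirror of a whole dataset ------------------------
flip_strand <- function(s) ifelse(s == "+", "-", ifelse(s == "-", "+", "."))

mirror_models <- function(models, L) {
  if (nrow(models) == 0) return(models)
  ex <- purrr::map(models$exons, function(e) {
    tibble::tibble(start = L - rev(e$end), end = L - rev(e$start))
  })
  transcript_tbl(models$transcript_id, models$chrom,
                 flip_strand(models$strand), ex, gene_id = models$gene_id)
}

mirror_sim <- function(sim) {
  L <- sim$chrom_len
  out <- sim
  out$annotation <- mirror_models(sim$annotation, L)
  out$genes <- mirror_models(sim$genes, L)
  out$coverage <- purrr::map(sim$coverage, function(cv) {
    list(
      plus = coverage_track(cv$minus$chrom, "+", rev(cv$minus$depth),
                            cv$minus$library_size, cv$minus$condition),
      minus = coverage_track(cv$plus$chrom, "-", rev(cv$plus$depth),
                             cv$plus$library_size, cv$plus$condition))
  })
  out$peaks <- dplyr::mutate(sim$peaks,
                             new_start = L - .data$end,
                             end = L - .data$start,
                             start = .data$new_start)[, names(sim$peaks)]
  out$truth <- dplyr::mutate(sim$truth,
                             new_as_start = L - .data$as_end,
                             as_end = L - .data$as_start,
                             as_start = .data$new_as_start,
                             as_strand = flip_strand(.data$as_strand),
                             new_es = L - .data$enhancer_end,
                             enhancer_end = L - .data$enhancer_start,
                             enhancer_start = .data$new_es,
                             boundary = L - .data$boundary)[, names(sim$truth)]
  out$fragments <- purrr::map(sim$fragments, mirror_models, L = L)
  out
}

# --- tiny default configs for unit tests -----------------------------------
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 6, n_antisense_loci = 3, seed = 11L), list(...))
  do.call(sim_config, args)
}

uniform_cfg <- function(...) {
  # Fully within-transcript-uniform expression: no noise, no terminal
  # attenuation, no isoform shift.
  args <- utils::modifyList(
    list(n_genes = 6, n_antisense_loci = 3, seed = 11L,
         noise_model = "none", terminal_attenuation_range = c(1, 1),
         short_isoform_fraction_on = 0, short_isoform_fraction_off = 0),
    list(...))
  do.call(sim_config, args)
}

# Fragments of a condition with rpkm + percentiles from its tracks.
fragments_with_percentiles <- function(sim, condition) {
  frags <- sim$fragments[[condition]]
  out <- list()
  for (st in c("+", "-")) {
    tr <- sim$coverage[[condition]][[if (st == "+") "plus" else "minus"]]
    sub <- frags[frags$strand == st, ]
    if (nrow(sub) == 0) next
    rec <- feature_rpkm(sub, tr)
    sub$rpkm <- rec$rpkm
    out[[st]] <- sub
  }
  dplyr::bind_rows(out) |> assign_percentiles()
}
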