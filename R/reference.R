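DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp_chars <- function(v) rev(chartr("ACGT", "TGCA", v))

#' Build the simulated reference with an inverted-repeat (palindrome) pair
#'
#' Generates a random reference sequence laid out as
#' `flank_left | arm1 | spacer | arm2 | dup_left | trp | dup_right |
#' flank_right`, where arm 2 is the reverse complement of arm 1 except at
#' divergent positions planted to achieve `arm_identity`, and at the two
#' cis-morphism sites, which carry distinct alleles between the arms.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `duptrp_reference` with elements:
#'   \describe{
#'     \item{seq}{character vector of bases (one per position).}
#'     \item{layout}{data.frame of segment records (`id`, `role`, `start`,
#'       `end`; 0-based half-open, contiguous and non-overlapping).}
#'     \item{sites}{data.frame of cis-morphism sites (`site_id`, `arm_offset`,
#'       `arm1_pos`, `arm2_pos`, `arm1_allele`, `arm2_allele`; alleles are
#'       expressed in the arm-1 forward frame and always differ).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' ref <- build_reference(sim_config(seed = 1, flank_len = 2000,
#'   dup_left_len = 1000, trp_len = 1500, dup_right_len = 1000,
#'   palindrome_arm_len = 1000, palindrome_spacer_len = 200,
#'   cis_morphism_offsets = c(300, 700)))
#' subset(ref$layout, role == "palindrome_arm_2")
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  A <- config$palindrome_arm_len
  seg_len <- c(flank_left = config$flank_len,
               palindrome_arm_1 = A,
               spacer = config$palindrome_spacer_len,
               palindrome_arm_2 = A,
               dup_left = config$dup_left_len,
               trp = config$trp_len,
               dup_right = config$dup_right_len,
               flank_right = config$flank_len)
  ends <- cumsum(seg_len)
  starts <- c(0L, ends[-length(ends)])
  role <- c("flank", "palindrome_arm_1", "spacer", "palindrome_arm_2",
            "dup", "trp", "dup", "flank")
  layout <- data.frame(id = names(seg_len), role = role,
                       start = as.integer(starts), end = as.integer(ends),
                       row.names = NULL, stringsAsFactors = FALSE)
  L <- ends[length(ends)]

  seq <- sample(DNA_BASES, L, replace = TRUE)
  a1s <- layout$start[layout$id == "palindrome_arm_1"]
  a2s <- layout$start[layout$id == "palindrome_arm_2"]
  arm1 <- seq[(a1s + 1):(a1s + A)]
  arm2 <- revcomp_chars(arm1)

  # cis-morphism sites: plant distinct alleles between the arms
  sites <- NULL
  cm <- config$cis_morphism_offsets
  if (!is.null(cm)) {
    arm1_pos <- a1s + cm                    # 0-based global
    arm2_pos <- a2s + (A - 1L - cm)
    arm1_allele <- arm1[cm + 1L]
    arm2_allele <- vapply(arm1_allele, function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
    # arm2 stores the complement on its own strand so that the arm-1-frame
    # reading of arm2 at the paralogous position yields arm2_allele
    arm2[A - cm] <- comp_base(arm2_allele)
    sites <- data.frame(site_id = paste0("cm", seq_along(cm)),
                        arm_offset = cm,
                        arm1_pos = as.integer(arm1_pos),
                        arm2_pos = as.integer(arm2_pos),
                        arm1_allele = arm1_allele,
                        arm2_allele = arm2_allele,
                        row.names = NULL, stringsAsFactors = FALSE)
  }

  # divergent positions for arm_identity, uniform at random, excluding sites
  n_div <- round((1 - config$arm_identity) * A)
  if (n_div > 0) {
    excl <- if (is.null(cm)) integer(0) else cm
    pool <- setdiff(seq_len(A) - 1L, excl)
    div <- sample(pool, n_div)
    old <- arm2[A - div]
    arm2[A - div] <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L),
                            character(1))
  }
  seq[(a2s + 1):(a2s + A)] <- arm2

  structure(list(seq = seq, layout = layout, sites = sites, config = config),
            class = "duptrp_reference")
}

#' @export
print.duptrp_reference <- function(x, ...) {
  cat("duptrp_reference:", length(x$seq), "bp,",
      nrow(x$layout), "layout segments,",
      if (is.null(x$sites)) 0L else nrow(x$sites), "cis-morphism sites\n")
  invisible(x)
}

layout_bounds <- function(layout, id) {
  i <- match(id, layout$id)
  c(layout$start[i], layout$end[i])
}
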