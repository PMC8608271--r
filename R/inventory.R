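#' ARPAbet phoneme inventory with phonetic attributes
#'
#' Lookup table mapping each phoneme label to the five phonetic attributes
#' used throughout the package: manner of articulation, place of
#' articulation, voicing, vowel height and vowel backness. Consonants carry
#' `"none"` for the two vowel attributes. The five manner classes are
#' vowel, plosive, fricative, nasal and approximant.
#'
#' @return data.frame with columns `phoneme`, `manner`, `place`, `voicing`,
#'   `height`, `backness`.
#' @export
#' @examples
#' inv <- phoneme_inventory()
#' table(inv$manner)
phoneme_inventory <- function() {
  p <- function(ph, manner, place, voicing, height = "none", backness = "none")
    data.frame(phoneme = ph, manner = manner, place = place, voicing = voicing,
               height = height, backness = backness)
  rbind(
    # vowels
    p("IY", "vowel", "none", "voiced", "high", "front"),
    p("IH", "vowel", "none", "voiced", "high", "front"),
    p("EH", "vowel", "none", "voiced", "mid", "front"),
    p("AE", "vowel", "none", "voiced", "low", "front"),
    p("AH", "vowel", "none", "voiced", "mid", "central"),
    p("ER", "vowel", "none", "voiced", "mid", "central"),
    p("AA", "vowel", "none", "voiced", "low", "back"),
    p("AO", "vowel", "none", "voiced", "low", "back"),
    p("OW", "vowel", "none", "voiced", "mid", "back"),
    p("UH", "vowel", "none", "voiced", "high", "back"),
    p("UW", "vowel", "none", "voiced", "high", "back"),
    # plosives
    p("P", "plosive", "bilabial", "unvoiced"),
    p("B", "plosive", "bilabial", "voiced"),
    p("T", "plosive", "alveolar", "unvoiced"),
    p("D", "plosive", "alveolar", "voiced"),
    p("K", "plosive", "velar", "unvoiced"),
    p("G", "plosive", "velar", "voiced"),
    # fricatives
    p("F", "fricative", "labiodental", "unvoiced"),
    p("V", "fricative", "labiodental", "voiced"),
    p("TH", "fricative", "dental", "unvoiced"),
    p("DH", "fricative", "dental", "voiced"),
    p("S", "fricative", "alveolar", "unvoiced"),
    p("Z", "fricative", "alveolar", "voiced"),
    p("SH", "fricative", "postalveolar", "unvoiced"),
    p("HH", "fricative", "glottal", "unvoiced"),
    # nasals
    p("M", "nasal", "bilabial", "voiced"),
    p("N", "nasal", "alveolar", "voiced"),
    p("NG", "nasal", "velar", "voiced"),
    # approximants
    p("L", "approximant", "alveolar", "voiced"),
    p("R", "approximant", "alveolar", "voiced"),
    p("W", "approximant", "velar", "voiced"),
    p("Y", "approximant", "palatal", "voiced")
  )
}

# Deterministic spectral prototype (length n_bands, non-negative, unit max)
# for a phoneme. Vowels: two formant-like Gaussian peaks whose positions
# follow height/backness; fricatives: high-frequency shelf by place;
# plosives: broadband with place-dependent tilt; nasals: low-frequency
# murmur; approximants: mid-low concentration. Deterministic by
# construction -- no RNG.
phoneme_prototype <- function(row, band_centers) {
  lb <- log2(band_centers)
  nb <- length(band_centers)
  gauss <- function(f0, bw) exp(-(lb - log2(f0))^2 / (2 * bw^2))
  prof <- switch(row$manner,
    vowel = {
      f1 <- switch(row$height, high = 320, mid = 520, low = 750, 500)
      f2 <- switch(row$backness, front = 2100, central = 1450, back = 950, 1400)
      gauss(f1, 0.35) + 0.7 * gauss(f2, 0.35)
    },
    fricative = {
      fc <- switch(row$place, alveolar = 4800, postalveolar = 3200,
                   dental = 4200, labiodental = 3800, glottal = 1500, 3500)
      0.15 + gauss(fc, 0.8)
    },
    plosive = {
      tilt <- switch(row$place, bilabial = -0.25, alveolar = 0.25, velar = 0, 0)
      0.55 + tilt * (lb - mean(lb)) / diff(range(lb)) * 2
    },
    nasal = gauss(280, 0.4) + 0.2 * gauss(2400, 0.5),
    approximant = gauss(420, 0.45) + 0.45 * gauss(1250, 0.4),
    rep(1, nb)
  )
  prof <- pmax(prof, 0)
  prof / max(prof)
}
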