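# Provenance notes for rwe_studies.csv

Nine real-world-evidence (RWE) studies of disease-modifying treatments in
relapsing-remitting multiple sclerosis, one row per study arm: number of
subjects (N), number of relapses, person-years of follow-up, and the
Expanded Disability Status Scale (EDSS, descriptive metadata only; NA where
the source table prints none). The annualised relapse rate (ARR) of an arm
is relapses / person-years.

The source is a typeset summary table in which the numeric columns of some
rows run together without separators. The readings below were fixed once,
against two internal consistency checks, and are never re-parsed:

1. **Constant within-study exposure ratio.** Within every study, person-years
   divided by N is constant across arms (all arms of a study share one mean
   follow-up duration). This resolves every ambiguous digit run uniquely:
   - Lanzillo 2012: py/N = 1.0 (both arms 42 subjects, 42 person-years).
   - Limmroth 2007: py/N = 2.0 (2188/1094, 2068/1034, 1110/555, 370/185).
   - Halpern 2011 (claims data, short follow-up): py/N = 0.25
     (72/288, 38/151, 82/329, 36/144, 117/469).
   - Patti 2006: py/N = 5.0 (570/114, 185/37, 85/17).
   - Rio 2005: py/N = 3.3 (356/107, 334/101).
   - Haas and Firzlaff 2005: py/N = 2.0.
   - Khan 2001: py/N = 1.5 (23/15, 51/34, 51/34, 59/39).
   - Trojano 2003: py/N = 2.0 (418/209, 338/169).
   - Carra 2003: py/N = 1.35 (35/26, 27/20, 27/20, 40/30).
2. **Plausible ARR magnitudes** (roughly 0.2-0.5 on active treatment, higher
   on placebo): e.g. Rio placebo 288/356 = 0.81, Halpern natalizumab
   21/72 = 0.29.

Cell-level decisions:
- **Haas and Firzlaff 2005**: the source prints a fourth data row
  (48 subjects, 59 relapses, 96 person-years, EDSS 2.36) with no treatment
  label, directly under the glatiramer acetate row (the study followed two
  glatiramer cohorts). It is merged into the glatiramer acetate arm:
  N = 79 + 48 = 127, relapses = 56 + 59 = 115, person-years = 158 + 96 = 254,
  EDSS = N-weighted mean (79*1.98 + 48*2.36)/127 = 2.12. Keeping it separate
  would duplicate a treatment within one study, which the arm-level model
  disallows.
- **Limmroth 2007 / Patti 2006 / Rio 2005 / Halpern 2011**: EDSS is printed
  only for the first arm of the study; remaining arms carry NA rather than a
  copied value.
- **Rio 2005**: accent dropped from the study label (ASCII-only fixture).

The true cell values would need the nine original publications to confirm;
these readings are the package's documented, internally consistent choice.
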