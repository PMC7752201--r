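Fixture data
============

themes_coresearchers.txt, themes_academics.txt
  Theme lists of the two analyst groups as printed in the published
  comparison tables (label: quote ids, one theme per line; academic
  subthemes listed as separate rows).

synthetic_grouping_coresearchers.csv, synthetic_grouping_academics.csv
  SYNTHETIC per-quote colour assignments. The original study's real
  per-quote grouping assignments are not available to this package;
  these stand-ins were constructed to be consistent with the
  dominant-grouping columns of the published theme tables (100% rows
  exactly; 9-of-11 and 5-of-7 splits for the two partial rows; a tie for
  the no-dominant-grouping row) and to cover all 89 quotes. Quotes not
  listed in any theme received arbitrary colours. They exercise the
  congruence statistics only and are not the study's data.

  Note: the published tie row lists 10 quote ids but a breakdown summing
  to 11 ("4 green; 4 pink; 3 blue"); with 10 quotes that exact breakdown
  is unattainable, so the synthetic assignment realizes a 4/4/2 tie.
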