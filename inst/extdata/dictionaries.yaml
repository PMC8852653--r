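# Example dictionary set.
#
# Each entry defines one concept ("code") as a list of regular
# expressions; a rule fires when a pattern matches a message, and the
# weight of the code on a message is the number of distinct rules that
# fire. The green_pass entry is the worked single-rule dictionary: it
# fires on "tessera verde", "tessere verdi", "pass verde" or
# "certificato verde", but not on "casa verde", "verderame" or
# "tessera del cinema".
- code: green_pass
  description: >
    COVID-19 certificate (vaccination/recovery/test) required to access
    venues; the discourse topic under study.
  patterns:
    - (tesser.\sverd.?|pass\sverd.?|certifica\w*\sverd.?)
- code: vaccine
  description: Vaccines and vaccination.
  patterns:
    - vaccin\w*
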