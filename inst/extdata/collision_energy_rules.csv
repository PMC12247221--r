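pattern,field,note
"CollisionEnergy:([0-9]+\.?[0-9]*)",either,"library-style token, e.g. CollisionEnergy:35"
"collision energy[ :=]*([0-9]+\.?[0-9]*)",either,"verbose annotation"
"(?<![A-Za-z])CE[ :=]+([0-9]+\.?[0-9]*)(?![0-9.]*\s*%)",either,"CE token; lookbehind excludes NCE, lookahead excludes percentages"
"([0-9]+\.?[0-9]*)\s*eV",either,"bare value with eV unit"
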