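>NOX2_synthetic synthetic NOX2-like reference scaffold (570 aa; not UniProtKB P04839): H101 H115 H119 T178 G179 H209 H222 planted, hydrophobic TM windows
DDMERCIPNQDYRGNNLPQGRMPVVFLFAMLMILIVMMLAVAFAIMVNFLEKKPTYMDTFILVILLMMMIIMMLFVIVVAVLEMCETTENMFKISMDAFIHVIVVLAIIFVMMFHIFLHAMMVMTPSWRGKCPDWYDAQCKWFNSHVENICFANMWCLVMAAMAMLAVLIFIAFLVMTGVIFIYHNLHNLDQPRKMHDMGFVAVFVLIHLVLLFVVAAFMAHVMFVILHPCYWVVHNALVIVMIILMLMMVIAIVLVFLLTMEQKEATCWVVDVNQMLTVHHSHMANYDEMICNSFCGTHSKMDMKPQAKIKHHIGMNQYSVMDDDLHPRFEFRCHQMHMMTYRHTTPMDENILQCNAVFQEANCPMCQHQRYSFCIDMPCTCKISSPAQGPGYDFKERGESNEIVSYYAWVGYWLIRWLNVTCNTIWPWGALYFHWKFVEDCGWLWHSMNDCDMRWHQNNKYAADVGDGGNTQGENVSFTGCSWAMHCERERLGEEPYYCQGRCNYAWTTQTVFQKYYKPEFQKPYSIWRQGFFCFNLDSCPYVCMIPLYPTKMGPEMGCQYDARVDCP
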