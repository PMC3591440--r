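>NOX5_synthetic synthetic NOX5-like sequence (765 aa; not UniProtKB Q96PH1): four canonical EF-hand loops then the NOX2-like scaffold
LCRKYRYRKEHIKDSKQSHSMDYPASEGLLLLLLLLLLLDKDGDGTITTKEQQGCCYECNKAVSLLLLLLLLLLLDKDGDGTITTKECHPARKAWCEIDMLLLLLLLLLLLDKDGDGTITTKEFMHEISIYVKACNLLLLLLLLLLLDKDGDGTITTKEREFADLHGTSIPRWRAHFVGQGNIQAWTQVKFIDEIDDMERCIPNQDYRGNNLPQGRMPVVFLFAMLMILIVMMLAVAFAIMVNFLEKKPTYMDTFILVILLMMMIIMMLFVIVVAVLEMCETTENMFKISMDAFIHVIVVLAIIFVMMFHIFLHAMMVMTPSWRGKCPDWYDAQCKWFNSHVENICFANMWCLVMAAMAMLAVLIFIAFLVMTGVIFIYHNLHNLDQPRKMHDMGFVAVFVLIHLVLLFVVAAFMAHVMFVILHPCYWVVHNALVIVMIILMLMMVIAIVLVFLLTMEQKEATCWVVDVNQMLTVHHSHMANYDEMICNSFCGTHSKMDMKPQAKIKHHIGMNQYSVMDDDLHPRFEFRCHQMHMMTYRHTTPMDENILQCNAVFQEANCPMCQHQRYSFCIDMPCTCKISSPAQGPGYDFKERGESNEIVSYYAWVGYWLIRWLNVTCNTIWPWGALYFHWKFVEDCGWLWHSMNDCDMRWHQNNKYAADVGDGGNTQGENVSFTGCSWAMHCERERLGEEPYYCQGRCNYAWTTQTVFQKYYKPEFQKPYSIWRQGFFCFNLDSCPYVCMIPLYPTKMGPEMGCQYDARVDCP
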