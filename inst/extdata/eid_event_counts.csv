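database,scope,n_events
original_1940_2004,all_eids,335
original_1940_2004,wildlife_zoonoses,145
updated_1940_2008,wildlife_zoonoses,224
updated_1940_2008,wildlife_zoonoses_post1970,147
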