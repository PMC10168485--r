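source,count
human_only,72
human_and_mouse,122
mouse_orthologues,540
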