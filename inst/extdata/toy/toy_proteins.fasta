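>toyA toy demonstration protein A
MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSG
>toyB toy demonstration protein B
GSHMLLKNNPPLIVFWWAAGGDDEEKKRRSSTTYYVVMMNNQQHHCCPPG
>toyC toy demonstration protein C
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDE
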