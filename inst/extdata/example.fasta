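>polyG
GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG
>polyK
KKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKKK
>polyE
EEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEEE
>VK25
VKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVKVK
>VE25
VEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVEVE
>VH25
VHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVHVH
>rand100
EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMTEPISQYHPNSAPGTKHWVSMLHWCLAMRLSNHIAWDMAQG
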