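concept_id,kind,synonym
cannabis,target,cannabis
cannabis,target,marijuana
cannabis,target,weed
cannabis,target,pot
cannabis,target,ganja
cannabis,target,hashish
cannabis,target,reefer
cannabis,target,mary jane
cannabis,target,thc
cannabis,target,bud
cannabis,target,dank
cannabis,target,blunt
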