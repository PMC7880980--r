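the
of
and
to
in
that
it
is
was
for
on
with
as
be
he
she
they
we
you
at
by
this
had
not
are
but
from
or
have
an
which
her
his
him
them
were
been
has
their
its
would
will
there
what
all
if
can
who
do
when
so
no
up
out
about
into
than
could
them
these
those
then
now
only
just
also
after
before
over
under
again
where
why
how
any
both
each
few
more
most
other
some
such
nor
too
very
shall
should
may
might
must
did
does
doing
being
having
because
until
while
during
through
between
above
below
down
off
once
here
our
ours
your
yours
my
mine
me
us
am
himself
herself
itself
themselves
myself
yourself
ourselves
whom
whose
although
though
unless
since
upon
within
without
toward
towards
against
among
along
across
behind
beyond
despite
except
versus
per
via
onto
whether
either
neither
yet
still
ever
never
always
perhaps
quite
rather
however
therefore
thus
hence
meanwhile
moreover
furthermore
nevertheless
nonetheless
anyway
else
much
many
own
same
less
least
own
shan
won
don
isn
aren
wasn
weren
hasn
haven
hadn
doesn
didn
wouldn
couldn
shouldn
mustn
needn
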